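16
guanine
N     -3.01644000    -0.96909000    -0.00000000
C     -1.72501000    -0.57260000     0.00000000
N     -0.76549000    -1.46014000     0.00000000
C      0.46736000    -0.90498000     0.00000000
N      1.65002000    -1.58094000     0.00000000
C      2.65071000    -0.64226000     0.00000000
N      2.17701000     0.58780000     0.00000000
C      0.81419000     0.42527000     0.00000000
C     -0.25747000     1.39560000     0.00000000
O     -0.12637000     2.61556000     0.00000000
N     -1.50858000     0.79237000     0.00000000
H     -3.20552000    -1.96361000     0.00000000
H     -3.79843000    -0.33353000    -0.00000000
H      1.75818000    -2.58422000     0.00000000
H      3.69783000    -0.91521000    -0.00000000
H     -2.28488000     1.43013000    -0.00000000
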