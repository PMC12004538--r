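15
adenine
N     -1.79066000     1.95165000    -0.00578000
C     -1.18764588     0.71496381     0.00234687
N     -1.97885987    -0.38355988     0.00718963
C     -1.38976394    -1.59990364     0.00862209
N     -0.07269699    -1.89548722     0.00582167
C      0.65884791    -0.77215669    -0.00124458
N      2.01970334    -0.67782206    -0.00315243
C      2.34134798     0.65272125    -0.00241904
N      1.26994981     1.41828011    -0.00015672
C      0.20617764     0.53580432     0.00060251
H     -2.79683000     1.98916000    -0.00351000
H     -1.21541000     2.78113000    -0.00536000
H     -2.06683000    -2.44940000     0.01888000
H      2.65815000    -1.45867000    -0.01139000
H      3.36669000     0.99923000     0.00080000
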