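15
thymine
C      2.66060000     0.99871000     0.04218000
C      1.20281606     0.68025891     0.00734584
C      0.22655667     1.59608153    -0.01024568
N     -1.09029875     1.23261775    -0.02474529
C     -1.51917768    -0.06604480    -0.02265426
O     -2.71031000    -0.35629000    -0.02721000
N     -0.53435628    -1.01065628    -0.00478864
C      0.80907999    -0.75494709     0.01066803
O      1.64330000    -1.65389000     0.01271000
H      2.83836000     2.07934000     0.04564000
H      3.16560000     0.58116000    -0.83470000
H      3.12442000     0.58344000     0.94287000
H      0.42866000     2.66288000    -0.01158000
H     -1.82042000     1.93585000    -0.04096000
H     -0.82235000    -1.97594000    -0.00304000
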