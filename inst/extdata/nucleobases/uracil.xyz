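12
uracil
O      2.31917000     0.85417000    -0.01050000
C      1.23939880     0.27508327    -0.01206317
C      1.16976897    -1.20039304    -0.01291067
C     -0.02998064    -1.78568993    -0.00157473
N     -1.17423709    -1.03873716     0.01059991
C     -1.18656697     0.33083758     0.01215298
O     -2.23236000     0.97064000     0.01527000
N      0.04102693     0.93138927     0.00055569
H      2.10221000    -1.74784000    -0.03028000
H     -0.14942000    -2.86421000    -0.00244000
H     -2.08411000    -1.48616000     0.02377000
H      0.06106000     1.93860000     0.00273000
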