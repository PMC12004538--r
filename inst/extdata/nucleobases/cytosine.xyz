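13
cytosine
N      2.37183000     1.01333000     0.15656000
C      1.20267934     0.30778654     0.08299267
C      1.24355868    -1.17391678     0.04865766
C      0.06020068    -1.78179541    -0.00644519
N     -1.08197288    -1.04122147    -0.02762177
C     -1.09967585     0.33283648     0.00490940
O     -2.18158000     0.91340000    -0.02755000
N      0.10118003     0.99491063     0.06191724
H      3.19110000     0.60893000    -0.27677000
H      2.24089000     1.99771000    -0.05789000
H      2.18902000    -1.69573000     0.06849000
H     -0.04763000    -2.86032000    -0.03145000
H     -1.99407000    -1.47659000    -0.05806000
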