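component,partner,e_pose,e_max,e_max_source
thiophene,A48,-4.9,-6.9,global_minimum_dimer
pyrimidine,A85,-8.3,-8.8,global_minimum_dimer
pyrimidin-4(3H)-one,A85,-8.0,-9.5,model_prediction
pyrimidine,G62,-4.6,-9.6,global_minimum_dimer
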