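"base","name","file","glycosidic_n"
"A","adenine","adenine.xyz",7
"G","guanine","guanine.xyz",5
"C","cytosine","cytosine.xyz",5
"T","thymine","thymine.xyz",4
"U","uracil","uracil.xyz",5
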