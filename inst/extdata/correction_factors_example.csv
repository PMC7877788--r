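zone,corner_type,era,f_design,f_size
Z1,section,e1,1.0,0.85
Z1,quarter-section,e1,0.9,0.85
Z1,section,e2,1.1,0.80
Z1,quarter-section,e2,1.0,0.80
Z2,section,e1,0.8,0.90
Z2,quarter-section,e1,0.75,0.90
Z2,section,e2,0.95,0.88
Z2,quarter-section,e2,0.9,0.88
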