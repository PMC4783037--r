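objective,Fish,BioA,BioB,BioPhys,Phys
physical_state,0.32,0,0.31,0.26,0.28
chemical_state,0.23,0,0.31,0.21,0.44
biological_state,0.45,1,0.39,0.53,0.28
aggregation,add,,mult,mult,add
synergy,1,,0.25,0.5,1
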