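analyte,M,Ka,Ke,dose_mg_kg
ABZSO,0.73,1.04,0.054,7.5
ABZSO2,0.52,1.02,0.05,7.5
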