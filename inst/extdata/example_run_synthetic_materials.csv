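material_id,label,mass_conc_mg_l,formula
CPLUS,Positive control (PHB),100,C4H6O2
ID016,Home-compostable bag,100,NA
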