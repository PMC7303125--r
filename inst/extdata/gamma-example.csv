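tissue,cpm,conversion,mass_g,elapsed_min
BAT,500000,0.00001,1.0,109.77
femur_BM,2000,0.00001,0.1,30
soleus,15000,0.00001,0.35,45
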