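drug,median_mg,min_mg,n_cycles,cycle_length
fu,770,598,12,14
lv,725,75,12,14
ir,300,208,12,14
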