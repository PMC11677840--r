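treatment,alive,nematode_killed,fungus_killed,indeterminate
control,113,0,2,2
fungi,37,0,15,1
halfmix,49,51,2,6
nematodes,56,62,1,2
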