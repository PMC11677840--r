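stage,alive,nematode_killed,fungus_killed,indeterminate
adult,26,4,1,1
larva,142,79,13,10
pupa,87,30,6,0
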