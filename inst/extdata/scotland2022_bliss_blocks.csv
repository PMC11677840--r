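scope,i_nf,i_bliss
Block5,0.285714286,0.5
Block9,0.764705882,0.6125
Block10,1,0.5
Block11,0.8,0.409090909
Block12,0,0.352941176
Block13,0.285714286,0.428571429
Block16,0.647058824,0.340697674
Block19,0.5,0.25
Block20,0.9,0.3125
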