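size_trimers,probability
1,0.50
2,0.21
3,0.12
5,0.095
8,0.06
20,0.015
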