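decay_class,density
1,0.54
2,0.45
3,0.36
4,0.26
5,0.17
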