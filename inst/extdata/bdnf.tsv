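genotype	controls	cases
wtwt	208	229
wtmt	131	83
mtmt	11	9
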