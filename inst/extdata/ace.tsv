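genotype	controls	cases
wtwt	64	34
wtmt	94	89
mtmt	51	82
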