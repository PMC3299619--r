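genotype	controls	cases
wtwt	448	238
wtmt	93	85
mtmt	4	17
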