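chrM	0	576	Dloop
chrM	16023	16569	Dloop
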