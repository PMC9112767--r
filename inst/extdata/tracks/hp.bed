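chrM	301	318	HP
chrM	454	464	HP
chrM	957	964	HP
chrM	2143	2152	HP
chrM	5892	5900	HP
chrM	8273	8283	HP
chrM	9537	9544	HP
chrM	12872	12883	HP
chrM	16182	16194	HP
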