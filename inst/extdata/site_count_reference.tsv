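modification	n_sites	n_fully_modified
m5C	47	10
Nm	29	7
D	47	0
m3C	9	1
m7G	17	17
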