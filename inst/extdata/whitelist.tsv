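modification	label
m5C	38
m5C	48
m5C	49
m5C	50
m5C	72
Nm	18
Nm	32
Nm	34
Nm	39
Nm	44
Nm	54
m7G	46
m3C	20
m3C	32
m3C	e2
D	16
D	17
D	20
D	20a
D	47
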