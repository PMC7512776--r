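% 8-airport example network: source	target	flights
A	B	5
A	D	1
A	F	3
B	A	4
B	C	2
B	D	3
B	E	3
C	B	4
C	E	2
C	H	5
D	A	2
D	B	5
D	E	4
E	B	3
E	C	3
E	D	4
E	F	2
E	G	1
F	A	1
F	G	3
F	E	2
G	E	1
G	F	1
G	H	2
H	C	1
H	G	4
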