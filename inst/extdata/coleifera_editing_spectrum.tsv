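aa_from	aa_to	codon_position	n
A	V	2	12
H	Y	1	23
L	F	1	13
P	F	1&2	20
P	L	2	89
P	S	1	33
Q	X	1	2
R	C	1	34
R	X	1	2
R	W	1	19
S	F	2	50
S	L	2	105
T	I	2	6
T	M	2	5
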