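characteristic	level	n
age	le65	231
age	gt65	249
age	unknown	10
sex	male	228
sex	female	262
stage	I	263
stage	II	115
stage	III	79
stage	IV	25
stage	unknown	8
t	T1	163
t	T2	263
t	T3	43
t	T4	18
t	Tx	3
n	N0	317
n	N1	92
n	N2	68
n	N3	2
n	Nx	11
m	M0	324
m	M1	24
m	Mx	142
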