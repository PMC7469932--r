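# Per-band CAPS patterns of the 7 orchard trees used for pollination
# assays; all individuals were heterozygous and amplified 2 bands.
# 'allele' is the identity assigned to each band (S_19-S_21 were novel).
individual	band	RsaI	MboI	HinfI	allele
1	1	L	H	Q	S_8
1	2	Q	P	R	S_19
12	1	O	L	I	S_4
12	2	I	M	K	S_9
13	1	O	L	I	S_4
13	2	I	M	K	S_9
14	1	O	Q	I	S_20
14	2	R	R	F	S_21
15	1	K	N	J	S_10
15	2	C	I	E	S_6
17	1	O	L	I	S_4
17	2	P	J	N	S_1
22	1	O	L	I	S_4
22	2	P	J	N	S_1
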