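# Individual digestion patterns of capuli S-RNase C2-C3 amplicons
# (per-enzyme pattern letter -> rounded band sizes, bp; ';'-separated)
pattern	enzyme	sizes
A	RsaI	200
A	MboI	200
A	HinfI	180;100
B	RsaI	200;160;150
B	MboI	210;200;190
B	HinfI	200
C	RsaI	210;140;100
C	MboI	240
C	HinfI	225;200
D	RsaI	210;180;160
D	MboI	300
D	HinfI	230;190;100
E	RsaI	230;200
E	MboI	300;100
E	HinfI	240
F	RsaI	240
F	MboI	360
F	HinfI	250;210
G	RsaI	240;225
G	MboI	460
G	HinfI	360;250;220
H	RsaI	290;170;100
H	MboI	465;250;230
H	HinfI	365
I	RsaI	330;210;180
I	MboI	490
I	HinfI	375;330;250;210
J	RsaI	370
J	MboI	520;430
J	HinfI	380
K	RsaI	430;250
K	MboI	550;415;250
K	HinfI	390;240
L	RsaI	475;360;290
L	MboI	600;470;300
L	HinfI	470
M	RsaI	620;210;195;170
M	MboI	615
M	HinfI	540
N	RsaI	790;510
N	MboI	760
N	HinfI	550;495
O	RsaI	940;220;170
O	MboI	1200
O	HinfI	550;350
P	RsaI	950
P	MboI	290;180;100
P	HinfI	580
Q	RsaI	280;120;90
Q	MboI	600;500;400;380
Q	HinfI	650;330;270
R	RsaI	220;200;110
R	MboI	430;100
R	HinfI	290;220
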