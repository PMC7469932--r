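# Curated catalogue of common restriction enzymes.
# Format: name  recognition-site with '^' marking the top-strand cut.
# Sites follow the REBASE prototype definitions.
RsaI	GT^AC
MboI	^GATC
HinfI	G^ANTC
AluI	AG^CT
HaeIII	GG^CC
TaqI	T^CGA
MseI	T^TAA
DdeI	C^TNAG
HhaI	GCG^C
NlaIII	CATG^
DraI	TTT^AAA
SspI	AAT^ATT
AseI	AT^TAAT
Tsp509I	^AATT
ApoI	R^AATTY
BstNI	CC^WGG
ScrFI	CC^NGG
StyI	CC^WWGG
AvaII	G^GWCC
HincII	GTY^RAC
EcoRI	G^AATTC
EcoRV	GAT^ATC
HindIII	A^AGCTT
BamHI	G^GATCC
PstI	CTGCA^G
NdeI	CA^TATG
XbaI	T^CTAGA
KpnI	GGTAC^C
SacI	GAGCT^C
SmaI	CCC^GGG
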