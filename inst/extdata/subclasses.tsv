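subclass	scaffold	n_chains	chain_linkages	default_adduct	head_ions
PC	C8H20NO6P	2	ester,ester	[M+H]+	ion:C5H15NO4P+:1.0
PE	C5H14NO6P	2	ester,ester	[M+H]+	nl:C2H8NO4P:1.0
PS	C6H14NO8P	2	ester,ester	[M+H]+	nl:C3H8NO6P:1.0
PG	C6H15O8P	2	ester,ester	[M+H]+	nl:C3H9O6P:1.0
PI	C9H19O11P	2	ester,ester	[M+H]+	nl:C6H13O9P:1.0
PA	C3H9O6P	2	ester,ester	[M+H]+	nl:H3O4P:1.0
DG	C3H8O3	2	ester,ester	[M+NH4]+	nl:H2O:0.5
TG	C3H8O3	3	ester,ester,ester	[M+NH4]+	
MG	C3H8O3	1	ester	[M+NH4]+	nl:H2O:0.5
LPC	C8H20NO6P	1	ester	[M+H]+	ion:C5H15NO4P+:1.0
LPE	C5H14NO6P	1	ester	[M+H]+	nl:C2H8NO4P:1.0
SM	C5H12NO3P	2	sphingoid,amide	[M+H]+	ion:C5H15NO4P+:1.0
Cer	H0	2	sphingoid,amide	[M+H]+	nl:H2O:0.8
Cer-NS	H0	2	sphingoid,amide	[M+H]+	nl:H2O:0.8
Cer-NDS	H0	2	sphingoid,amide	[M+H]+	nl:H2O:0.8
Cer-EOS	H0	3	sphingoid,amide,ester	[M+H]+	nl:H2O:0.8
HexCer	C6H10O5	2	sphingoid,amide	[M+H]+	nl:C6H10O5:0.8
HexCer-NS	C6H10O5	2	sphingoid,amide	[M+H]+	nl:C6H10O5:0.8
CAR	C7H15NO3	1	ester	[M+H]+	
SPB	H0	1	sphingoid	[M+H]+	nl:H2O:0.8
PE-N(FA)	C5H14NO6P	3	amide,ester,ester	[M+H]+	
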