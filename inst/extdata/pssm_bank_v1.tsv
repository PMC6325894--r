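kinase	acceptor_class	offset	residue	weight
ProD_01	ST	-2	P	1
ProD_01	ST	1	P	2
ProD_02	ST	1	P	2.05
ProD_02	ST	2	P	1
ProD_03	ST	1	P	2.1
ProD_03	ST	3	K	1
ProD_04	ST	-3	L	1
ProD_04	ST	1	P	2.15
ProD_05	ST	1	P	2.2
ProD_05	ST	2	R	1
ProD_06	ST	-2	S	1
ProD_06	ST	1	P	2.25
ProD_07	ST	1	P	2.3
ProD_07	ST	3	P	1
ProD_08	ST	1	P	2.35
ProD_08	ST	2	L	1
ProD_09	ST	-3	P	1
ProD_09	ST	1	P	2.4
ProD_10	ST	-2	V	1
ProD_10	ST	1	P	2.45
Baso_01	ST	-3	R	2
Baso_01	ST	-2	R	1.2
Baso_02	ST	-3	R	2.05
Baso_02	ST	-2	K	1.2
Baso_03	ST	-4	R	1.2
Baso_03	ST	-3	R	2.1
Baso_04	ST	-3	R	2.15
Baso_04	ST	2	F	1.2
Baso_05	ST	-3	R	2.2
Baso_05	ST	-2	L	1.2
Baso_06	ST	-3	K	2.25
Baso_06	ST	-2	K	1.2
Baso_07	ST	-4	K	1.2
Baso_07	ST	-3	K	2.3
Baso_08	ST	-3	K	2.35
Baso_08	ST	-2	R	1.2
Baso_09	ST	-3	K	2.4
Baso_09	ST	2	L	1.2
Baso_10	ST	-4	K	1.2
Baso_10	ST	-3	K	2.45
Acid_01	ST	1	E	1.2
Acid_01	ST	2	E	0.8
Acid_01	ST	3	E	2
Acid_02	ST	1	D	1.2
Acid_02	ST	2	E	0.8
Acid_02	ST	3	D	2.05
Acid_03	ST	1	E	1.2
Acid_03	ST	2	E	0.8
Acid_03	ST	3	E	2.1
Acid_04	ST	1	D	1.2
Acid_04	ST	2	E	0.8
Acid_04	ST	3	D	2.15
Acid_05	ST	1	E	1.2
Acid_05	ST	2	E	0.8
Acid_05	ST	3	E	2.2
Acid_06	ST	1	D	1.2
Acid_06	ST	2	E	0.8
Acid_06	ST	3	D	2.25
OthST_01	ST	-1	L	1.55
OthST_01	ST	4	F	1.2
OthST_02	ST	1	F	1.6
OthST_02	ST	4	L	1.2
OthST_03	ST	-4	M	1.2
OthST_03	ST	-1	F	1.65
OthST_04	ST	2	W	1.7
OthST_04	ST	4	L	1.2
TyrK_01	Y	-3	E	2
TyrK_01	Y	3	I	1.2
TyrK_02	Y	-4	D	2.05
TyrK_02	Y	3	V	1.2
TyrK_03	Y	-3	E	2.1
TyrK_03	Y	3	L	1.2
TyrK_04	Y	-2	D	2.15
TyrK_04	Y	3	I	1.2
TyrK_05	Y	-3	E	2.2
TyrK_05	Y	3	F	1.2
TyrK_06	Y	-4	E	2.25
TyrK_06	Y	3	V	1.2
TyrK_07	Y	-3	D	2.3
TyrK_07	Y	3	I	1.2
TyrK_08	Y	-2	E	2.35
TyrK_08	Y	3	P	1.2
TyrK_09	Y	-4	D	2.4
TyrK_09	Y	3	L	1.2
TyrK_10	Y	-3	E	2.45
TyrK_10	Y	3	V	1.2
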