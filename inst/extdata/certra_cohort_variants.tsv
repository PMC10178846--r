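subject_id	aa_pos	ref_aa	alt_aa
P01	132	S	L
P02	132	S	L
P03	132	S	L
P04	132	S	L
P05	135	S	P
P06	135	S	P
P07	138	S	C
P08	138	S	C
P09	141	S	?
P10	166	T	A
P11	166	T	A
P12	166	T	A
P13	166	T	A
P14	240	D	?
P15	243	G	R
P16	243	G	R
P17	243	G	R
P18	243	G	R
P19	247	T	?
P20	251	T	?
P21	326	V	F
P22	329	A	P
P23	330	L	V
P24	330	L	P
P25	59	D	E
P26	93	S	R
P27	182	F	L
P28	366	R	T
P29	382	I	V
P30	424	E	G
P31	449	A	V
P32	500	S	L
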