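variant_id	human_aa_change	mouse_aa_change	nucleotide_change	insight_class	prior_label
POLY-A	POLY-A	NA	NA	1	non_pathogenic
POLY-B	POLY-B	NA	NA	1	non_pathogenic
POLY-C	POLY-C	NA	NA	1	non_pathogenic
POLY-D	POLY-D	NA	NA	1	non_pathogenic
L1087R	L1087R	L1085R	NA	3	non_pathogenic
V397E	NA	V397E	NA	5	pathogenic
L448P	NA	L448P	NA	5	pathogenic
R1332Q	NA	R1332Q	NA	5	pathogenic
G1139S	G1139S	G1137S	NA	3	pathogenic
R511G	R511G	R510G	c.1531A>G	3	uncertain
A587P	A587P	A586P	c.1759G>C	4	pathogenic
G686D	G686D	G683D	c.2057G>A	4	pathogenic
F706S	F706S	F703S	c.2117T>C	NA	uncertain
L1063R	L1063R	L1060R	c.3188T>G	4	pathogenic
E1193K	E1193K	E1191K	c.3577G>A	3	uncertain
T1219D	T1219D	T1217D	c.3655_3656delACinsGA	NA	uncertain
T1219I	T1219I	T1217I	c.3656C>T	3	uncertain
A25S	A25S	NA	NA	NA	uncertain
E221D	E221D	NA	NA	NA	uncertain
G670R	G670R	NA	NA	NA	uncertain
R922Q	R922Q	NA	NA	NA	uncertain
c.3438+6T>C	NA	NA	c.3438+6T>C	NA	uncertain
R128L	R128L	NA	NA	3	uncertain
R468H	R468H	NA	NA	2	non_pathogenic
V509A	V509A	NA	NA	2	non_pathogenic
Y556F	Y556F	NA	NA	3	uncertain
P623A	P623A	NA	NA	2	non_pathogenic
S666P	S666P	NA	NA	3	uncertain
E983Q	E983Q	NA	NA	3	uncertain
R1095C	R1095C	NA	NA	3	uncertain
T1255M	T1255M	NA	NA	3	uncertain
R1304K	R1304K	NA	NA	2	non_pathogenic
S285I	S285I	NA	NA	3	uncertain
G566R	G566R	G565R	NA	3	non_pathogenic
T1142M	T1142M	NA	NA	3	uncertain
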