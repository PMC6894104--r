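category	i2b2_training	i2b2_validation	uf_training	uf_validation	uf_test
DATE	9067	3104	2056	774	1872
NAME	5472	1868	856	356	771
AGE	1507	490	158	86	164
ID	1142	364	156	41	137
PHONE	406	128	50	28	47
WEB	6	1	0	0	4
INSTITUTE	1926	592	128	72	119
STREET	280	72	25	6	21
CITY	502	152	43	26	45
ZIP	276	76	34	11	20
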