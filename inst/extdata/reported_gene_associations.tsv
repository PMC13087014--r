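gene	beta	se	t	p_spatial	r2
APP	-0.55	0.17	-3.23	0.008	0.16
BIN1	-0.72	0.24	-3.01	0.02	0.14
GBA	-0.65	0.16	-4.03	0.002	0.22
MAPT	-0.65	0.18	-3.70	0.003	0.20
PINK1	-0.62	0.14	-4.51	0.0001	0.27
SNCA	-0.55	0.16	-3.39	0.001	0.17
TMEM175	-0.69	0.29	-2.40	0.02	0.09
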