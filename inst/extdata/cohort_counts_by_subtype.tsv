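variable	level	BLIA	BLIS	LAR	MES
family_history	yes	18	17	8	0
family_history	no	20	29	14	4
group	White	10	12	9	2
group	Hispanic	14	25	6	2
group	AfricanAmerican	5	5	2	0
group	Asian	9	4	8	0
grade	2	2	5	10	0
grade	3	36	41	13	4
stage	1	13	12	6	2
stage	2	22	31	11	2
stage	3	3	3	8	0
node_positive	yes	10	5	10	1
node_positive	no	26	41	14	3
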