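variable	level	White	Hispanic	AfricanAmerican	Asian
family_history	yes	11	18	7	8
family_history	no	23	30	5	13
detection	lump	23	34	7	13
detection	mammogram	8	12	5	5
detection	other	3	2	0	3
grade	2	3	5	3	6
grade	3	28	43	9	15
stage	1	10	15	4	4
stage	2	21	28	6	13
stage	3	3	5	2	4
tumor_size	T1	10	16	6	8
tumor_size	T2	20	29	4	10
tumor_size	T3	4	2	2	2
tumor_size	T4	0	1	0	1
node_positive	yes	7	7	3	9
node_positive	no	26	41	8	11
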