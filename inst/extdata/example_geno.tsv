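id	m1
ID_1	1
ID_2	1
ID_3	2
ID_4	1
ID_5	1
ID_6	2
ID_7	2
ID_8	0
ID_9	1
ID_10	1
ID_11	0
ID_12	0
ID_13	0
ID_14	2
ID_15	0
ID_16	1
ID_17	2
ID_18	2
ID_19	1
ID_20	0
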