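id	value
ID_1	140
ID_2	122
ID_3	116
ID_4	114
ID_5	112
ID_6	108
ID_7	108
ID_8	105
ID_9	105
ID_10	102
ID_11	101
ID_12	99
ID_13	98
ID_14	97
ID_15	95
ID_16	94
ID_17	91
ID_18	86
ID_19	84
ID_20	76
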