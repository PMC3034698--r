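lg	Am01	Am02	Am03	Am04	Am05	Am06	Am07	Am08	Am09	Am10	Am11	Am12	Am13	Am14	Am15	Am16	Un	assigned
B01	26	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	Am01
B02	0	17	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2	Am02
B03	1	0	12	0	0	0	0	1	0	1	0	0	0	0	0	1	1	Am03
B04	0	0	1	4	0	0	0	0	0	0	0	0	0	0	0	0	0	Am04
B05	0	0	0	0	19	0	1	0	0	0	0	0	0	0	0	0	0	Am05
B06	2	0	1	0	0	14	0	0	0	0	0	1	0	0	0	0	1	Am06
B07	1	0	0	0	0	0	3	0	0	0	2	0	0	0	0	0	2	Am07
B08	0	0	0	0	0	0	4	7	0	0	0	0	0	0	0	0	1	Am07,Am08
B09	4	0	0	0	0	5	0	0	12	0	0	0	0	0	0	0	0	Am01,Am06,Am09
B10	0	0	0	0	0	0	1	0	0	8	0	0	0	0	0	0	1	Am10
B11	6	0	0	0	1	0	0	0	0	0	7	0	0	0	0	0	2	Am01,Am11
B12	0	0	0	0	0	0	0	0	0	0	0	8	0	0	0	7	1	Am12,Am16
B13	0	0	0	0	0	1	0	0	0	0	0	0	16	0	0	0	2	Am13
B14	0	0	0	1	0	0	0	0	0	0	0	0	0	10	0	0	0	Am14
B15	0	0	0	0	0	0	1	0	0	0	0	7	0	0	6	0	0	Am12,Am15
B16	1	0	0	0	0	0	0	2	0	0	0	0	0	0	0	0	2	-
B17	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	-
B18	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	-
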