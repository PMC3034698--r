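lg	length_cm	n_markers	n_distorted	avg_dist_cm	corrected_length_cm
B01	121.01	38	5	3.18	127.38
B02	125.20	37	6	3.38	131.97
B03	96.35	38	1	2.54	101.42
B04	80.66	20	1	4.03	88.73
B05	102.84	30	5	3.43	109.69
B06	171.70	35	6	4.91	181.51
B07	161.43	33	0	4.89	171.21
B08	91.64	30	5	3.05	97.75
B09	109.48	32	6	3.42	116.32
B10	126.46	35	9	3.61	133.69
B11	116.30	35	2	3.32	122.94
B12	111.39	34	3	3.28	117.94
B13	105.74	31	5	3.41	112.56
B14	73.44	21	4	3.50	80.43
B15	96.55	33	13	2.93	102.40
B16	77.87	16	1	4.87	87.61
B17	83.14	10	2	8.31	99.77
B18	51.01	8	1	6.38	63.77
SUM/MEAN	1902.21	516	75	4.02	2047.09
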