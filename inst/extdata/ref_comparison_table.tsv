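lg	n_syntenic_pairs	synteny_q_cm	synteny_t_cm	ratio_qt	synteny_pct	n_rearranged_blocks	rearranged_q_cm	rearranged_pct	n_insertions	conserved_pct
B01	12	24.692	57.9	0.43	19.38	10	51.283	40.26	2	59.65
B02	12	63.332	170.18	0.37	47.99	3	34.315	26.00	0	73.99
B03	2	1.179	22.03	0.05	1.16	4	15.43	15.21	4	16.38
B04	1	25.333	32.66	0.78	28.55	2	18.614	20.98	1	49.53
B05	6	15.837	25.25	0.63	14.44	11	55.54	50.63	1	65.07
B06	3	8.859	16.37	0.54	4.88	8	55.006	30.30	3	35.19
B07	1	0.506	1.74	0.29	0.30	0	0	0.00	1	0.30
B08	2	2.058	0.51	4.04	2.11	1	18.258	18.68	0	20.78
B09	11	33.858	95.42	0.35	29.11	4	27.785	23.89	4	52.99
B10	3	18.244	17.15	1.06	13.65	3	41.25	30.86	1	44.50
B11	6	17.201	26.36	0.65	13.99	2	20.886	16.99	1	30.98
B12	6	16.823	28.27	0.60	14.26	5	41.498	35.18	0	49.45
B13	9	46.896	122.42	0.38	41.66	5	7.1	6.31	1	47.97
B14	5	17.977	57.11	0.31	22.35	3	36.91	45.89	1	68.24
B15	4	10.327	21.29	0.49	10.08	4	7.885	7.70	1	17.78
B16	0	0	0	NA	0	0	0	0	0	0.00
B17	0	0	0	NA	0	0	0	0	0	0.00
B18	0	0	0	NA	0	0	0	0	0	0.00
SUM/MEAN	83	303.029	681.56	0.45	17.59	65	429.815	24.59	21	42.19
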