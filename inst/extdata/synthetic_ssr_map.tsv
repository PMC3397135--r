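marker	chrom	position_mb
synmk_c1_01	1	5.07
synmk_c1_02	1	7.05
synmk_c1_03	1	16.76
synmk_c1_04	1	17.15
synmk_c1_05	1	19.04
synmk_c1_06	1	25.65
synmk_c1_07	1	28.08
synmk_c1_08	1	40.27
synmk_c1_09	1	40.96
synmk_c1_10	1	43.94
synmk_c2_01	2	2.2
synmk_c2_02	2	3.83
synmk_c2_03	2	17.36
synmk_c2_04	2	17.75
synmk_c2_05	2	19.74
synmk_c2_06	2	34.22
synmk_c2_07	2	48.2
synmk_c2_08	2	51.63
synmk_c2_09	2	52.71
synmk_c2_10	2	54.67
synmk_c3_01	3	0.51
synmk_c3_02	3	10.25
synmk_c3_03	3	11.4
synmk_c3_04	3	11.71
synmk_c3_05	3	29.9
synmk_c3_06	3	30.59
synmk_c3_07	3	32.39
synmk_c3_08	3	33.13
synmk_c3_09	3	47.13
synmk_c4_01	4	4.72
synmk_c4_02	4	12.18
synmk_c4_03	4	21.92
synmk_c4_04	4	36.84
synmk_c4_05	4	47.3
synmk_c4_06	4	51.52
synmk_c4_07	4	52.61
synmk_c5_01	5	2.46
synmk_c5_02	5	8.11
synmk_c5_03	5	10.57
synmk_c5_04	5	16.17
synmk_c5_05	5	31.14
synmk_c5_06	5	41.78
synmk_c5_07	5	52.89
synmk_c6_01	6	8.83
synmk_c6_02	6	10.92
synmk_c6_03	6	31.6
synmk_c6_04	6	33.37
synmk_c6_05	6	47.38
synmk_c6_06	6	52.99
synmk_c7_01	7	1.04
synmk_c7_02	7	32.54
synmk_c7_03	7	37.34
synmk_c7_04	7	43.23
synmk_c7_05	7	51.11
synmk_c8_01	8	5.23
synmk_c8_02	8	13.06
synmk_c8_03	8	20.52
synmk_c8_04	8	52.82
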