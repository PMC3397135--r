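group	n_genotypes	n_pairs_tested	n_significant
southern_caerulea	99	179	10
northern_caerulea	69	179	5
hemicycla	44	179	1
lowland_falcata	63	179	6
upland_falcata	99	179	2
overall	374	179	15
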