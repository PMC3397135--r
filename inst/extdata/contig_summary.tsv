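contig	n_amplicons	alignment_length_bp	coverage_min	coverage_max	n_snps	n_ns_snps	n_indels
CCoAoMT	4	1185	0	1886	31	3	9
F5H_exon1	2	723	0	1499	16	3	0
F5H_exon2	1	594	0	287	39	5	0
PAL1_exon1	1	377	0	207	14	1	0
PAL1_exon2	4	1481	0	2014	52	0	0
COMT_exon1	1	415	0	1182	11	2	0
COMT_contig2	3	1224	0	1536	31	0	1
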