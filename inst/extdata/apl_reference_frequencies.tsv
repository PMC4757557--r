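# n_ref: 2504
# Carrier frequencies of the 15 recurrence-enriched genes of the APL
# extended cohort (n = 25) and the 1000 Genomes reference population.
gene	cohort_frequency_pct	reference_frequency_pct
HERC1	44	3
CACNA2D3	12	0.9
CACNA1E	16	0.6
MYCBP2	20	2
KIAA0317	12	0.4
SMC1A	12	0
USP9X	12	0.09
TOP3B	12	0.9
PRICKLE2	8	0.1
IKZF1	8	0
LYN	8	0
STAG2	8	0.01
PTPN11	8	0.01
U2AF1	8	0
TMEM56	8	0
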