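# Functional-category labels of the recurrence-enriched APL genes.
gene	category
HERC1	ubiquitination
CACNA2D3	transmembrane protein
CACNA1E	protein kinase
MYCBP2	ubiquitination
KIAA0317	ubiquitination
SMC1A	cohesin complex
USP9X	spliceosome
TOP3B	transcription factor/regulator
PRICKLE2	other cell functions
IKZF1	transcription factor/regulator
LYN	tyrosine-protein kinase
STAG2	cohesin complex
PTPN11	transmembrane protein
U2AF1	spliceosome
TMEM56	transcription factor/regulator
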