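# toy STRING-style export: splicing-factor interactions
gene_a	gene_b	combined_score
SF3B1	SF3A2	0.95
SF3B1	DHX15	0.88
SF3B1	U2AF2	0.91
SF3B1	SF3B3	0.99
DHX15	PRPF19	0.72
U2AF2	SRSF1	0.80
SRSF1	SRSF1	0.99
SF3B1	SF3A2	0.95
SF3B6	SF3B1	0.35
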