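gene1	gene2	coefficient
STAT1	STAT1	0.42
STAT1	IRF1	0.55
STAT1	CD274	0.38
STAT1	BST2	0.47
STAT1	ACSL5	0.21
STAT1	CLIC2	0.18
STAT1	HIST2H2AA3	0.12
STAT1	FAM83D	-0.09
STAT1	METAP2	0.26
IRF1	CD274	0.33
IRF1	METAP2	0.24
BST2	CD274	0.15
FAM83D	IRF1	-0.11
CD274	CLIC2	0.08
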