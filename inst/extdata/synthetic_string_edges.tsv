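node_a	node_b	score	channel
EGFR	SHC1	0.999	experimental
EGFR	GAB1	0.996	experimental
EGFR	MAPK1	0.988	database
EGFR	MAPK3	0.984	database
SHC1	GAB1	0.975	experimental
GAB1	MAPK1	0.951	experimental
MAPK1	MAPK3	0.993	database
EGFR	ARHGAP35	0.912	experimental
SHC1	MAPK3	0.905	coexpression
GAB1	ARHGAP35	0.842	coexpression
EGFR	ANXA1	0.74	textmining
SHC1	ANXA1	0.95	textmining
BCAR1	EGFR	0.93	experimental
PIK3R1	EGFR	0.97	database
PIK3CA	PIK3R1	0.999	database
BCAR1	SHC1	0.88	experimental
ANXA1	MAPK1	0.61	coexpression
ARHGAP35	MAPK3	0.55	coexpression
PIK3R1	GAB1	0.945	experimental
BCAR1	PIK3CA	0.91	textmining
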