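HSA04611	KEGG synthetic platelet activation set	GP6	GP5	GP1BA	FCER1G	SYK	PLCG2	PIK3CA	AKT1	NOS3	PRKCA	PRKG1	ITGA2B	ITGB3	SRC	MAPK1	MYH9	collagen	fibrinogen	thromboxane a2
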