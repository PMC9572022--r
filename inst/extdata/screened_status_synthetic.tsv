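symbol	status
F13A1	screened_negative
FCER1G	screened_positive_external_celltype
PIK3CA	screened_positive_external_celltype
MAPK1	screened_positive_external_celltype
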