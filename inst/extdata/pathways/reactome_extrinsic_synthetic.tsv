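#pathway	Reactome	R-HSA-140834
# Synthetic stand-in for the extrinsic pathway of fibrin clot formation.
source	source_class	interaction	target	target_class
F3	protein	binding	F7	protein
F7	protein	activation	F10	protein
TFPI	protein	inhibition	F3	protein
TFPI	protein	inhibition	F10	protein
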