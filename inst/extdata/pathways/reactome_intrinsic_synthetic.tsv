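#pathway	Reactome	R-HSA-140837
# Synthetic stand-in for the intrinsic (contact) pathway of fibrin clot
# formation: membership hand-assembled, edges schematic.
source	source_class	interaction	target	target_class
F12	protein	activation	F11	protein
F12	protein	activation	KLKB1	protein
KLKB1	protein	activation	F12	protein
KNG1	protein	binding	KLKB1	protein
F11	protein	activation	F9	protein
F9	protein	activation	F10	protein
F8	protein	binding	F9	protein
VWF	protein	binding	F8	protein
PROC	protein	inhibition	F8	protein
PROS1	protein	binding	PROC	protein
SERPINC1	protein	inhibition	F10	protein
SERPING1	protein	inhibition	F12	protein
A2M	protein	inhibition	KLKB1	protein
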