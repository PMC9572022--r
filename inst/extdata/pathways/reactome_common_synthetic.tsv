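#pathway	Reactome	R-HSA-140875
# Synthetic stand-in for the common pathway of fibrin clot formation;
# fibrinogen and fibrin are named (non-gene) clot constituents.
source	source_class	interaction	target	target_class
F10	protein	activation	F2	protein
F5	protein	binding	F10	protein
F2	protein	activation	fibrinogen	metabolite
fibrinogen	metabolite	activation	fibrin	metabolite
F2	protein	activation	F13A1	protein
F13A1	protein	activation	fibrin	metabolite
F2	protein	activation	F8	protein
PROC	protein	inhibition	F5	protein
PROC	protein	inhibition	F8	protein
SERPINC1	protein	inhibition	F2	protein
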