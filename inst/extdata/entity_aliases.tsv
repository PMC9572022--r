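alias	symbol
apc	PROC
activated protein c	PROC
thrombin	F2
tissue factor	F3
fviii	F8
fviiia	F8
gpvi	GP6
plasma kallikrein	KLKB1
protein kinase c	PRKCA
myosin	MYH9
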