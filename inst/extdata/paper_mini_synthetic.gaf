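!gaf-version: 2.2
! synthetic GO cellular-component annotations for the paper_mini corpus
SYN	SYN:F2	F2	located_in	GO:0005615	SYN:0000001	IDA		C	F2		protein	taxon:9606	20220101	SYN		
SYN	SYN:F5	F5	located_in	GO:0005615	SYN:0000001	IDA		C	F5		protein	taxon:9606	20220101	SYN		
SYN	SYN:F7	F7	located_in	GO:0005615	SYN:0000001	IDA		C	F7		protein	taxon:9606	20220101	SYN		
SYN	SYN:F8	F8	located_in	GO:0005615	SYN:0000001	IDA		C	F8		protein	taxon:9606	20220101	SYN		
SYN	SYN:F9	F9	located_in	GO:0005615	SYN:0000001	IDA		C	F9		protein	taxon:9606	20220101	SYN		
SYN	SYN:F10	F10	located_in	GO:0005615	SYN:0000001	IDA		C	F10		protein	taxon:9606	20220101	SYN		
SYN	SYN:F11	F11	located_in	GO:0005615	SYN:0000001	IDA		C	F11		protein	taxon:9606	20220101	SYN		
SYN	SYN:F12	F12	located_in	GO:0005615	SYN:0000001	IDA		C	F12		protein	taxon:9606	20220101	SYN		
SYN	SYN:F13A1	F13A1	located_in	GO:0005615	SYN:0000001	IDA		C	F13A1		protein	taxon:9606	20220101	SYN		
SYN	SYN:KLKB1	KLKB1	located_in	GO:0005615	SYN:0000001	IDA		C	KLKB1		protein	taxon:9606	20220101	SYN		
SYN	SYN:KNG1	KNG1	located_in	GO:0005615	SYN:0000001	IDA		C	KNG1		protein	taxon:9606	20220101	SYN		
SYN	SYN:VWF	VWF	located_in	GO:0005615	SYN:0000001	IDA		C	VWF		protein	taxon:9606	20220101	SYN		
SYN	SYN:PROC	PROC	located_in	GO:0005615	SYN:0000001	IDA		C	PROC		protein	taxon:9606	20220101	SYN		
SYN	SYN:PROS1	PROS1	located_in	GO:0005615	SYN:0000001	IDA		C	PROS1		protein	taxon:9606	20220101	SYN		
SYN	SYN:MMP9	MMP9	located_in	GO:0005615	SYN:0000001	IDA		C	MMP9		protein	taxon:9606	20220101	SYN		
SYN	SYN:SERPINC1	SERPINC1	located_in	GO:0005615	SYN:0000001	IDA		C	SERPINC1		protein	taxon:9606	20220101	SYN		
SYN	SYN:SERPING1	SERPING1	located_in	GO:0005615	SYN:0000001	IDA		C	SERPING1		protein	taxon:9606	20220101	SYN		
SYN	SYN:A2M	A2M	located_in	GO:0005615	SYN:0000001	IDA		C	A2M		protein	taxon:9606	20220101	SYN		
SYN	SYN:TFPI	TFPI	located_in	GO:0005615	SYN:0000001	IDA		C	TFPI		protein	taxon:9606	20220101	SYN		
SYN	SYN:F3	F3	located_in	GO:0005886	SYN:0000001	IDA		C	F3		protein	taxon:9606	20220101	SYN		
SYN	SYN:GP6	GP6	located_in	GO:0005886	SYN:0000001	IDA		C	GP6		protein	taxon:9606	20220101	SYN		
SYN	SYN:GP5	GP5	located_in	GO:0005886	SYN:0000001	IDA		C	GP5		protein	taxon:9606	20220101	SYN		
SYN	SYN:GP1BA	GP1BA	located_in	GO:0005886	SYN:0000001	IDA		C	GP1BA		protein	taxon:9606	20220101	SYN		
SYN	SYN:ITGA2B	ITGA2B	located_in	GO:0005886	SYN:0000001	IDA		C	ITGA2B		protein	taxon:9606	20220101	SYN		
SYN	SYN:ITGB3	ITGB3	located_in	GO:0005886	SYN:0000001	IDA		C	ITGB3		protein	taxon:9606	20220101	SYN		
SYN	SYN:CLEC1B	CLEC1B	located_in	GO:0005886	SYN:0000001	IDA		C	CLEC1B		protein	taxon:9606	20220101	SYN		
SYN	SYN:TLR4	TLR4	located_in	GO:0005886	SYN:0000001	IDA		C	TLR4		protein	taxon:9606	20220101	SYN		
SYN	SYN:FCER1G	FCER1G	located_in	GO:0005886	SYN:0000001	IDA		C	FCER1G		protein	taxon:9606	20220101	SYN		
SYN	SYN:SYK	SYK	located_in	GO:0005829	SYN:0000001	IDA		C	SYK		protein	taxon:9606	20220101	SYN		
SYN	SYN:AKT1	AKT1	located_in	GO:0005829	SYN:0000001	IDA		C	AKT1		protein	taxon:9606	20220101	SYN		
SYN	SYN:NOS3	NOS3	located_in	GO:0005829	SYN:0000001	IDA		C	NOS3		protein	taxon:9606	20220101	SYN		
SYN	SYN:PLCG2	PLCG2	located_in	GO:0005829	SYN:0000001	IDA		C	PLCG2		protein	taxon:9606	20220101	SYN		
SYN	SYN:PRKCA	PRKCA	located_in	GO:0005829	SYN:0000001	IDA		C	PRKCA		protein	taxon:9606	20220101	SYN		
SYN	SYN:SRC	SRC	located_in	GO:0005829	SYN:0000001	IDA		C	SRC		protein	taxon:9606	20220101	SYN		
SYN	SYN:MYH9	MYH9	located_in	GO:0005829	SYN:0000001	IDA		C	MYH9		protein	taxon:9606	20220101	SYN		
SYN	SYN:MAPK1	MAPK1	located_in	GO:0005829	SYN:0000001	IDA		C	MAPK1		protein	taxon:9606	20220101	SYN		
SYN	SYN:PIK3CA	PIK3CA	located_in	GO:0005829	SYN:0000001	IDA		C	PIK3CA		protein	taxon:9606	20220101	SYN		
SYN	SYN:PRKG1	PRKG1	located_in	GO:0005829	SYN:0000001	IDA		C	PRKG1		protein	taxon:9606	20220101	SYN		
SYN	SYN:VWF	VWF	located_in	GO:0005737	SYN:0000001	IDA		C	VWF		protein	taxon:9606	20220101	SYN		
SYN	SYN:F2	F2	NOT|located_in	GO:0005829	SYN:0000001	IDA		C	F2		protein	taxon:9606	20220101	SYN		
SYN	SYN:F2	F2	enables	GO:0004252	SYN:0000001	IDA		F	F2		protein	taxon:9606	20220101	SYN		
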