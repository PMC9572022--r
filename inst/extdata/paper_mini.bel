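# paper_mini: compact hand-curated corpus of heme effects on the blood
# coagulation system and platelet activation signaling. Statements encode
# published findings (heme binding affinities, dose/route/cell-type
# context); citations are synthetic placeholders.
SET DOCUMENT Name = "paper_mini"
SET DOCUMENT Version = "1.0"
DEFINE NAMESPACE HGNC
DEFINE NAMESPACE CHEBI
DEFINE NAMESPACE GO
DEFINE NAMESPACE MESH
DEFINE NAMESPACE TEXT

# --- coagulation cascade: direct heme binding ---
SET Citation = "90000001"
SET Evidence = "High-affinity heme binding to coagulation factor VIII inhibits its function."
SET Setting = "in vitro"
SET KD = "1.9 nM"
SET Note = "K_D reading A: FVIII 1.9 nM / FVIIIa 12.7 nM"
complex(a(CHEBI:heme), p(HGNC:F8)) =| act(p(HGNC:F8))
SET KD = "12.7 nM"
SET Note = "K_D reading B (swapped): FVIII 12.7 nM / FVIIIa 1.9 nM"
complex(a(CHEBI:heme), p(HGNC:F8)) =| act(p(HGNC:F8))
UNSET Note
SET Evidence = "Heme binding to FVIII abolishes the FVIII-FIX interaction."
SET KD = "1.9 nM"
complex(a(CHEBI:heme), p(HGNC:F8)) =| complex(p(HGNC:F8), p(HGNC:F9))
UNSET KD
SET Evidence = "VWF protects FVIII from heme-driven inhibition."
p(HGNC:VWF) -| bp(GO:"negative regulation of blood coagulation")
SET Citation = "90000002"
SET Evidence = "Direct heme binding completely abrogates activated protein C function."
SET Dose = "up to 100 µM"
SET KD = "400 nM"
complex(a(CHEBI:heme), p(HGNC:PROC)) =| act(p(HGNC:PROC))
UNSET KD
UNSET Dose
SET Citation = "90000003"
SET Evidence = "Fibrinogen binds heme; heme promotes fibrinogen binding to platelets and clot formation."
SET Dose = "up to 500 µM"
SET KD = "3.3 µM"
complex(a(CHEBI:heme), a(TEXT:fibrinogen)) -> bp(GO:"platelet aggregation")
UNSET KD
UNSET Dose

# --- extrinsic pathway: tissue factor induction ---
SET Citation = "90000004"
SET Evidence = "Heme induces tissue factor expression in endothelial cells."
SET CellType = "endothelial cell"
SET Dose = "up to 100 µM"
a(CHEBI:heme) -> p(HGNC:F3)
SET Evidence = "Heme induces functionally active TF in whole blood ex vivo."
SET Setting = "ex vivo"
SET CellType = "leukocyte"
SET Dose = "30 µM"
a(CHEBI:heme) -> p(HGNC:F3)
SET Evidence = "Intravenous heme injection triggers TF-dependent coagulation activation in mice."
SET Setting = "in vivo"
UNSET CellType
SET Species = "10090"
SET Dose = "100 µmol/kg"
SET Route = "intravenous"
a(CHEBI:heme) -> p(HGNC:F3)
SET Evidence = "Retroorbital heme injection triggers coagulation activation in mice."
SET Dose = "35 µmol/kg"
SET Route = "retroorbital"
a(CHEBI:heme) -> p(HGNC:F3)
UNSET Route
UNSET Species

# --- intrinsic / contact pathway ---
SET Citation = "90000005"
SET Evidence = "Plasma kallikrein is activated in the presence of heme in plasma samples."
SET Setting = "in vitro"
SET Dose = "up to 24 nmol"
a(CHEBI:heme) -> act(p(HGNC:KLKB1))
SET Evidence = "Heme-triggered autoactivation of factor XII has been suggested."
a(CHEBI:heme) -> act(p(HGNC:F12))
UNSET Dose
SET Evidence = "FXII immunoblockage does not reduce heme-triggered coagulation activation in vivo."
SET Setting = "in vivo"
SET Species = "10090"
SET Dose = "up to 35 µmol/kg"
SET Route = "retroorbital"
a(CHEBI:heme) reg act(p(HGNC:F12))
UNSET Route
UNSET Species
UNSET Dose

# --- VWF axis ---
SET Citation = "90000006"
SET Evidence = "Heme increases VWF expression, string formation and secretion from Weibel-Palade bodies."
SET Setting = "in vitro"
SET CellType = "endothelial cell"
SET Dose = "up to 100 µM"
a(CHEBI:heme) -> p(HGNC:VWF)
SET Evidence = "Heme injection increases VWF in vivo."
SET Setting = "in vivo"
UNSET CellType
SET Species = "10090"
SET Dose = "3.2 µmol/kg"
SET Route = "intravenous"
a(CHEBI:heme) -> p(HGNC:VWF)
UNSET Route
UNSET Species
SET Evidence = "Heme upregulates MMP9, which regulates VWF digestion."
SET Setting = "in vitro"
SET CellType = "endothelial cell"
SET Dose = "up to 60 µM"
a(CHEBI:heme) -> p(HGNC:MMP9)
p(HGNC:MMP9) -| p(HGNC:VWF)
UNSET Dose
UNSET CellType

# --- common pathway ---
SET Citation = "90000007"
SET Evidence = "Heme abolishes the prothrombinase reaction via direct inhibition of cofactor FVa."
SET Setting = "in vivo"
SET Dose = "4 mg/kg"
SET Route = "intravenous"
a(CHEBI:heme) =| act(p(HGNC:F5))
UNSET Route
UNSET Dose
SET Evidence = "Strong heme binding to thrombin suggested; amidolytic effect not reproduced."
SET Setting = "in vitro"
a(CHEBI:heme) -- p(HGNC:F2)
SET Evidence = "Heme drives fibrinogen crosslinking and polymer formation, leading to clot formation."
SET Dose = "up to 500 µM"
a(CHEBI:heme) -> a(TEXT:fibrin)
a(TEXT:fibrinogen) -> bp(GO:"blood coagulation")
UNSET Dose

# --- platelet activation signaling ---
SET Citation = "90000008"
SET Evidence = "GPVI binds heme with low affinity; heme induces platelet aggregation."
SET CellType = "platelet"
SET Dose = "up to 115 µM"
SET KD = "29.4 µM"
complex(a(CHEBI:heme), p(HGNC:GP6)) -> bp(GO:"platelet activation")
UNSET KD
SET Evidence = "Heme exposure associates with Syk phosphorylation in platelets."
a(CHEBI:heme) -> act(p(HGNC:SYK))
SET Evidence = "Heme exposure associates with PLCgamma2 phosphorylation in platelets."
SET Dose = "up to 50 µM"
a(CHEBI:heme) -> act(p(HGNC:PLCG2))
UNSET Dose
SET Evidence = "CLEC2 activation by heme contributes to platelet signaling."
a(CHEBI:heme) -> act(p(HGNC:CLEC1B))
SET Evidence = "Heme activates platelets with Akt phosphorylation, dependent on TLR4."
SET Dose = "2.5 µM"
a(CHEBI:heme) -> act(p(HGNC:AKT1))
p(HGNC:TLR4) reg bp(GO:"platelet activation")
UNSET Dose
SET Citation = "90000009"
SET Evidence = "Heme activates PKC in neutrophils."
SET CellType = "neutrophil"
SET Dose = "up to 20 µM"
a(CHEBI:heme) -> act(p(HGNC:PRKCA))
UNSET Dose
SET Evidence = "Heme influences eNOS production."
UNSET CellType
a(CHEBI:heme) reg p(HGNC:NOS3)
SET Evidence = "Src is activated by heme in epithelial cells."
SET CellType = "epithelial cell"
a(CHEBI:heme) -> act(p(HGNC:SRC))
UNSET CellType
SET Evidence = "Heme-induced oxidation of myosin; platelet shape change shown in vitro."
SET Dose = "up to 300 µM"
a(CHEBI:heme) reg p(HGNC:MYH9)
a(CHEBI:heme) -> bp(GO:"platelet shape change")
UNSET Dose
SET Citation = "90000010"
SET Evidence = "Heme-driven platelet aggregation through fibrinogen binding to alphaIIbbeta3."
SET CellType = "platelet"
SET Dose = "11 µM"
a(TEXT:fibrinogen) -> complex(p(HGNC:ITGA2B), p(HGNC:ITGB3))
UNSET Dose
SET Evidence = "Heme-triggered endothelial collagen expression with increased platelet aggregation."
SET Setting = "ex vivo"
UNSET CellType
SET Dose = "1 mM"
a(CHEBI:heme) -> a(TEXT:collagen)
UNSET Dose
SET Evidence = "Interrelation of heme with thromboxane A2 in platelets."
SET Setting = "in vitro"
SET CellType = "platelet"
a(CHEBI:heme) -> a(CHEBI:"thromboxane A2")
UNSET CellType

# --- clinical outcomes of heme injection ---
SET Citation = "90000011"
SET Evidence = "Administered heme causes thrombophlebitis and prothrombotic effects."
SET Setting = "in_vivo"
SET Species = "9606"
a(CHEBI:heme) -> path(MESH:Thrombophlebitis)
a(CHEBI:heme) -> path(MESH:Thrombosis)
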