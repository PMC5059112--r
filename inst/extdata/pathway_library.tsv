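construct_id	pathway	protein	activation_strategy	variant_note	validation_assay	barcode	role
KRAS_G12V	Ras-MAPK	KRAS	G12V mutation		Western (P-ERK)	ATCA	pathway_activator
HRAS_G12V	Ras-MAPK	HRAS	G12V mutation		Western (P-ERK)	TGAT	pathway_activator
MEK1_DD	Ras-MAPK	MEK1	S218D, S222D mutations		Western (P-ERK)	AATC	pathway_activator
PIK3CA_myr	PI3K-AKT-mTOR	PIK3CA	myr-FLAG tag		Western (P-AKT)	GCGT	pathway_activator
AKT1_myr	PI3K-AKT-mTOR	AKT1	myr-FLAG tag		Western (P-AKT, P-S6K1)	AAAA	pathway_activator
RHEB_Q64L	PI3K-AKT-mTOR	Rheb	Q64L mutation		Western (P-S6K1)	GACC	pathway_activator
IKKA_EE	NF-kB	IKKalpha	S176E, S180E mutations		Reporter (NF-kB_Luc)	CCGA	pathway_activator
IKKB_EE	NF-kB	IKKbeta	S177E, S181E mutations		Reporter (NF-kB_Luc)	GGGG	pathway_activator
JAK2_V617F	JAK-STAT	JAK2	V617F mutation		Reporter (Stat_Luc)	TTTT	pathway_activator
STAT3_CA	JAK-STAT	Stat3	A662C, N664C, V667L mutations		Reporter (Stat_Luc)	CACG	pathway_activator
CTNNB1_4A	Wnt/beta-catenin	beta-catenin	S33A, S37A, T41A, S45A mutations		Reporter (TCF-LEF_Luc)	TAGT	pathway_activator
GSK3B_K85A	Wnt/beta-catenin	GSK3beta	K85A mutation		Reporter (TCF-LEF_Luc)	GAAG	pathway_activator
CTNNB1_S33Y	Wnt/beta-catenin	beta-catenin	S33Y mutation		Reporter (TCF-LEF_Luc)	CCAG	pathway_activator
JNK2_WT	JNK	JNK2	WT overexpression		Reporter (AP1_Luc)	TATG	pathway_activator
JNK2_MKK7	JNK	JNK2	Mkk7 fusion		Reporter (AP1_Luc)	GGCT	pathway_activator
MEK5_DD	ERK5	MEK5	S311D, T315D mutations		Western (ERK5 laddering)	GTCG	pathway_activator
MEK5_myr	ERK5	MEK5	myr-FLAG tag		Western (ERK5 laddering)	AGCC	pathway_activator
NOTCH1_ICD	Notch	Notch1	intracellular domain only		Reporter (HES1_Luc)	ACGC	pathway_activator
NOTCH3_ICD	Notch	Notch3	intracellular domain only		Reporter (HES1_Luc)	AGAG	pathway_activator
P38_WT	p38	p38 (MAPK14)	WT overexpression		Western (P-p38)	ATGT	pathway_activator
MKK6_EE	p38	MKK6	S207E, T211E mutations		Western (P-p38)	TCCT	pathway_activator
GLI2_TRUNC	Hedgehog	Gli2	truncation		Reporter (Gli_Luc)	GCAC	pathway_activator
SMO_W535L	Hedgehog	SmoM2	W535L mutation		Reporter (Gli_Luc)	GGAA	pathway_activator
TGFBR1_WT	TGF-beta	TGFbetaR1	WT overexpression		Immunofluorescence (P-Smad2/3)	CGAC	pathway_activator
BCL2_WT	Apoptosis (BCL-2 family)	BCL2	WT overexpression	mitochondrial (intrinsic) arm	Western (cleaved caspase 9)	TTGA	pathway_activator
BCLXL_WT	Apoptosis (BCL-2 family)	BCL-XL	WT overexpression	mitochondrial (intrinsic) arm	Western (cleaved caspase 9)	GCTG	pathway_activator
CASP8_C360A	Apoptosis (BCL-2 family)	Caspase-8	C360A mutation	death receptor (extrinsic) arm	Western (cleaved caspase 8)	TGGC	pathway_activator
CASP3_C163A	Apoptosis (BCL-2 family)	Caspase-3	C163A mutation	common effector arm	Western (cleaved caspase 3/7)	TACA	pathway_activator
ESR1_Y537S	Estrogen receptor	ERalpha	Y537S mutation		Reporter (ERE_Luc)	GTAT	pathway_activator
AR_V7	Androgen receptor	AR	V7 variant		Western (ARE_Luc)	TCAA	pathway_activator
YAP2_5SA	Hippo	YAP2	FLAG-YAP2 (5SA)		Immunofluorescence (nuclear YAP)	CATA	pathway_activator
LATS2_KD	Hippo	Lats2	kinase dead (K697R)		Immunofluorescence (nuclear YAP)	ACCG	pathway_activator
TP53_R175H	p53	p53	dominant negative R175H mutant		Reporter (p53_Luc)	GTTA	pathway_activator
HRAS_G12V_E37G	Ral	Hras	G12V, E37G mutations			CTTC	pathway_activator
RGL2_CAAX	Ral	Rgl2	Rgl2-CAAX			GAGA	pathway_activator
RALA_G23V	Ral	RalA	G23V mutation	two forms - full and mature peptide		GATT	pathway_activator
CTRL_HCRED		HcRed	inert fluorophore			GCCA	negative_control
CTRL_LUC		luciferase	inert enzyme			CGTG	negative_control
CTRL_MEK1_DD	Ras-MAPK	MEK1	S218D, S222D mutations	spike-in mirroring the MEK1-DD activator; on-pathway control under MEK inhibition	Western (P-ERK)	CGCA	positive_control
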