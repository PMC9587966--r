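gene	category
ADORA2A	receptor
BTLA	co-inhibitor
BTN3A1	ligand
BTN3A2	ligand
CD27	co-stimulator
CD274	co-inhibitor
CD276	co-inhibitor
CD28	co-stimulator
CD40	co-stimulator
CD40LG	co-stimulator
CD70	co-stimulator
CD80	co-stimulator
CD86	co-stimulator
CTLA4	co-inhibitor
EDNRB	receptor
ENTPD1	other
GZMA	other
HAVCR2	co-inhibitor
HLA-A	antigen presentation
HLA-B	antigen presentation
HLA-C	antigen presentation
HLA-DPA1	antigen presentation
HLA-DPB1	antigen presentation
HLA-DQA1	antigen presentation
HLA-DQA2	antigen presentation
HLA-DQB1	antigen presentation
HLA-DQB2	antigen presentation
HLA-DRA	antigen presentation
HLA-DRB1	antigen presentation
HMGB1	other
ICAM1	cell adhesion
ICOS	co-stimulator
ICOSLG	co-stimulator
IDO1	co-inhibitor
IFNA1	ligand
IFNA2	ligand
IFNG	ligand
IL10	ligand
IL12A	ligand
IL13	ligand
IL1A	ligand
IL1B	ligand
IL2	ligand
IL2RA	receptor
IL4	ligand
ITGB2	cell adhesion
KIR2DL1	co-inhibitor
KIR2DL2	co-inhibitor
KIR2DL3	co-inhibitor
LAG3	co-inhibitor
MICA	antigen presentation
MICB	antigen presentation
PDCD1	co-inhibitor
PDCD1LG2	co-inhibitor
PRF1	other
SELP	cell adhesion
SLAMF7	co-stimulator
TGFB1	ligand
TIGIT	co-inhibitor
TLR4	receptor
TNF	ligand
TNFRSF14	co-stimulator
TNFRSF18	co-stimulator
TNFRSF4	co-stimulator
TNFRSF9	co-stimulator
TNFSF4	co-stimulator
TNFSF9	co-stimulator
VEGFA	ligand
VEGFB	ligand
VTCN1	co-inhibitor
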