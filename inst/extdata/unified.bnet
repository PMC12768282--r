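# Unified heart-field + cardiomyocyte-subtype network (21 nodes).
# The GATA4/6 nodes of the two submodels are merged; the heart-field outputs
# GATA4/6 and NKX2-5 feed the subtype module through NR2F2 and IRX4.
# FGF8 and its exogenous driver are carried over from the adapted heart-field
# network as a sink branch that does not perturb the published attractors
# (reconstruction placeholder).
targets, factors
EX_WNT, EX_WNT
EX_BMP2, EX_BMP2
EX_FGF8, EX_FGF8
BMP2, EX_BMP2 & !WNT
WNT, EX_WNT
FOXC1_2, WNT
ISL1, FOXC1_2
MESP1, WNT & !FOXC1_2
GATA4_6, GATA4_6 | MESP1 | ISL1
NKX2_5, GATA4_6
TBX1, FOXC1_2
TBX5, NKX2_5 & !ISL1
FGF8, EX_FGF8 & FOXC1_2
NOTCH, NOTCH
RA, RA
NR2F2, RA & GATA4_6
HAND2, IRX4 | GATA4_6
IRX4, HAND2 & NKX2_5 & !NR2F2
HEY2, NOTCH & GATA4_6 & !NR2F2
MYL2, IRX4 & !NR2F2
MYL7, NR2F2 & !HEY2
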