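# Heart field specification network (11 nodes), adapted single-exogen form.
# EX_BMP2 is clamped active in all conditions (lateral plate mesoderm);
# EX_WNT selects the second heart field branch.
# Rules are a constrained reconstruction validated against the published
# steady states (FHF, SHF, null); see the model provenance notes.
targets, factors
EX_WNT, EX_WNT
EX_BMP2, EX_BMP2
BMP2, EX_BMP2 & !WNT
WNT, EX_WNT
FOXC1_2, WNT
ISL1, FOXC1_2
MESP1, WNT & !FOXC1_2
NKX2_5, GATA4_6
TBX1, FOXC1_2
TBX5, NKX2_5 & !ISL1
GATA4_6, GATA4_6 | MESP1 | ISL1
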