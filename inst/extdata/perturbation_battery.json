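{
  "conditions": [
    {"key": "WNT=0,RA=1", "clamps": {"EX_WNT": 0, "RA": 1}, "cell_type": "FHF_aCM"},
    {"key": "WNT=0,RA=0", "clamps": {"EX_WNT": 0, "RA": 0}, "cell_type": "FHF_vCM"},
    {"key": "WNT=1,RA=1", "clamps": {"EX_WNT": 1, "RA": 1}, "cell_type": "SHF_aCM"},
    {"key": "WNT=1,RA=0", "clamps": {"EX_WNT": 1, "RA": 0}, "cell_type": "SHF_vCM"}
  ],
  "experiments": [
    {"id": "WT", "label": "wild type", "ko": [], "oe": [],
     "expected": {"WNT=0,RA=1": 1, "WNT=0,RA=0": 1, "WNT=1,RA=1": 1, "WNT=1,RA=0": 1},
     "literature": "wild-type differentiation produces all four heart-field-specific subtypes"},
    {"id": "i", "label": "HAND2 KO", "ko": ["HAND2"], "oe": [],
     "expected": {"WNT=0,RA=1": 1, "WNT=0,RA=0": 1, "WNT=1,RA=1": 1, "WNT=1,RA=0": 0},
     "literature": "HAND2 knockout results in no right ventricle"},
    {"id": "ii", "label": "COUP-TFII KO", "ko": ["NR2F2"], "oe": [],
     "expected": {"WNT=0,RA=1": 0, "WNT=0,RA=0": 1, "WNT=1,RA=1": 0, "WNT=1,RA=0": 1},
     "literature": "COUP-TFII knockout results in no atrial cardiomyocytes"},
    {"id": "iii", "label": "TBX5 KO", "ko": ["TBX5"], "oe": [],
     "expected": {"WNT=0,RA=1": 0, "WNT=0,RA=0": 1, "WNT=1,RA=1": 0, "WNT=1,RA=0": 1},
     "literature": "TBX5 knockout results in no atrial cardiomyocytes"},
    {"id": "iv", "label": "NKX2-5 KO", "ko": ["NKX2_5"], "oe": [],
     "expected": {"WNT=0,RA=1": 1, "WNT=0,RA=0": 0, "WNT=1,RA=1": 1, "WNT=1,RA=0": 1},
     "literature": "NKX2.5 knockout results in no left ventricle"},
    {"id": "v", "label": "NKX2-5 + HAND2 KO", "ko": ["NKX2_5", "HAND2"], "oe": [],
     "expected": {"WNT=0,RA=1": 1, "WNT=0,RA=0": 0, "WNT=1,RA=1": 1, "WNT=1,RA=0": 0},
     "literature": "NKX2.5 with HAND2 knockout gives no ventricle"},
    {"id": "vi", "label": "HEY2 KO", "ko": ["HEY2"], "oe": [],
     "expected": {"WNT=0,RA=1": 1, "WNT=0,RA=0": 0, "WNT=1,RA=1": 1, "WNT=1,RA=0": 1},
     "literature": "HEY2 knockout mice cannot develop a normal left ventricle"},
    {"id": "vii", "label": "HEY2 OE", "ko": [], "oe": ["HEY2"],
     "expected": {"WNT=0,RA=1": 0, "WNT=0,RA=0": 1, "WNT=1,RA=1": 0, "WNT=1,RA=0": 1},
     "literature": "HEY2 overexpression in atrial cardiomyocytes represses atrial genes"}
  ]
}
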