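{
  "comment": "Synthetic stand-in key-residue scoring table (IsPETase 1-based numbering). Critical rules cover the catalytic triad (S160/D206/H237) and the PETase-specific disulfide (C203/C239): any substitution is inhibiting ('*' = every non-reference residue) and absence carries the critical penalty. Standard rules carry activity-enhancing substitutions reported for engineered IsPETase variants (ThermoPETase S121E/D186H/R280A; DuraPETase L117F/Q119Y/T140D/G165A/I168R/A180I/S188Q/S214H; S238F) and inhibiting back-wall substitutions at A89/W159 (charged Glu/His back wall).",
  "weights": {
    "standard": 1,
    "critical": 3,
    "absence_penalty_critical": -3
  },
  "thresholds": {
    "medium": 4,
    "high": 9
  },
  "rules": [
    {"position": 160, "reference_residue": "S", "positive": [], "negative": ["*"], "class": "catalytic_triad"},
    {"position": 206, "reference_residue": "D", "positive": [], "negative": ["*"], "class": "catalytic_triad"},
    {"position": 237, "reference_residue": "H", "positive": [], "negative": ["*"], "class": "catalytic_triad"},
    {"position": 203, "reference_residue": "C", "positive": [], "negative": ["*"], "class": "disulfide"},
    {"position": 239, "reference_residue": "C", "positive": [], "negative": ["*"], "class": "disulfide"},
    {"position":  89, "reference_residue": "A", "positive": [], "negative": ["E", "Q"], "class": "standard"},
    {"position": 159, "reference_residue": "W", "positive": [], "negative": ["H", "E"], "class": "standard"},
    {"position": 117, "reference_residue": "L", "positive": ["F"], "negative": [], "class": "standard"},
    {"position": 119, "reference_residue": "Q", "positive": ["Y"], "negative": [], "class": "standard"},
    {"position": 121, "reference_residue": "S", "positive": ["E", "D"], "negative": [], "class": "standard"},
    {"position": 140, "reference_residue": "T", "positive": ["D"], "negative": [], "class": "standard"},
    {"position": 165, "reference_residue": "G", "positive": ["A"], "negative": [], "class": "standard"},
    {"position": 168, "reference_residue": "I", "positive": ["R"], "negative": [], "class": "standard"},
    {"position": 180, "reference_residue": "A", "positive": ["I"], "negative": [], "class": "standard"},
    {"position": 186, "reference_residue": "D", "positive": ["H"], "negative": [], "class": "standard"},
    {"position": 188, "reference_residue": "S", "positive": ["Q"], "negative": [], "class": "standard"},
    {"position": 214, "reference_residue": "S", "positive": ["H"], "negative": [], "class": "standard"},
    {"position": 238, "reference_residue": "S", "positive": ["F"], "negative": [], "class": "standard"},
    {"position": 280, "reference_residue": "R", "positive": ["A"], "negative": [], "class": "standard"}
  ]
}
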