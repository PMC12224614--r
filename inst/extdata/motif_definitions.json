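{
  "comment": "Default M1-M5 motif definitions. Patterns are PROSITE-style; anchor = match start; distance bounds are anchor separations measured on the IsPETase reference and widened by +/-10 residues. The optional (Y) inside the DxDxR(Y)xxFxC block is expressed as the bounded wildcard x(2,3) between R and F (present: 3 residues, absent: 2).",
  "components": [
    {
      "name": "nucleophile_elbow",
      "pattern": "G-x-S-x-G",
      "role": "helix-4 nucleophile elbow carrying the catalytic serine (S160); serine at offset 2",
      "serine_offset": 2
    },
    {
      "name": "glycine_quad",
      "pattern": "G-G-G-G",
      "role": "conserved four-glycine motif embedding helix-4 into the core (G162-G165)"
    },
    {
      "name": "aromatic_clamp_1",
      "pattern": "[WYF]-[DNE]-S-[ST]",
      "role": "aromatic clamp of the PET substrate (W185 region)"
    },
    {
      "name": "catalytic_asp",
      "pattern": "E-x-D-[SGAT]",
      "role": "catalytic aspartate of the triad (D206 region)"
    },
    {
      "name": "catalytic_his",
      "pattern": "G-G-x-H-[SA]",
      "role": "catalytic histidine completing the triad (H237 region)"
    },
    {
      "name": "pg_g_yf",
      "pattern": "[PG]-G-[YF]",
      "role": "upstream aromatic clamp / oxyanion hole (P85-G86-Y87)"
    },
    {
      "name": "ser_met",
      "pattern": "S-M",
      "role": "oxyanion hole: methionine directly after the catalytic serine (S160-M161); must share its serine with the nucleophile elbow",
      "serine_offset": 0
    },
    {
      "name": "dxdxr_block",
      "pattern": "D-x-D-x-R-x(2,3)-F-x-C",
      "role": "conserved DxDxR(Y)xxFxC block packing the final helix to the core (D263-C273)"
    },
    {
      "name": "disulfide_cys",
      "pattern": "C-[AG]-N-S",
      "role": "cysteine of the PETase-specific internal disulfide bond (C239)"
    }
  ],
  "tiers": [
    {
      "tier": "M1",
      "components": ["nucleophile_elbow"],
      "constraints": []
    },
    {
      "tier": "M2",
      "components": ["nucleophile_elbow", "glycine_quad", "aromatic_clamp_1",
                     "catalytic_asp"],
      "constraints": []
    },
    {
      "tier": "M3",
      "components": ["nucleophile_elbow", "glycine_quad", "aromatic_clamp_1",
                     "catalytic_asp", "catalytic_his"],
      "constraints": [
        {"from": "nucleophile_elbow", "to": "glycine_quad",     "min_sep": 0,  "max_sep": 14},
        {"from": "nucleophile_elbow", "to": "aromatic_clamp_1", "min_sep": 17, "max_sep": 37},
        {"from": "aromatic_clamp_1",  "to": "catalytic_asp",    "min_sep": 9,  "max_sep": 29},
        {"from": "catalytic_asp",     "to": "catalytic_his",    "min_sep": 20, "max_sep": 40}
      ]
    },
    {
      "tier": "M4",
      "components": ["pg_g_yf", "nucleophile_elbow", "glycine_quad",
                     "aromatic_clamp_1", "catalytic_asp", "catalytic_his"],
      "constraints": [
        {"from": "nucleophile_elbow", "to": "glycine_quad",     "min_sep": 0,  "max_sep": 14},
        {"from": "nucleophile_elbow", "to": "aromatic_clamp_1", "min_sep": 17, "max_sep": 37},
        {"from": "aromatic_clamp_1",  "to": "catalytic_asp",    "min_sep": 9,  "max_sep": 29},
        {"from": "catalytic_asp",     "to": "catalytic_his",    "min_sep": 20, "max_sep": 40},
        {"from": "pg_g_yf",           "to": "nucleophile_elbow","min_sep": 63, "max_sep": 83}
      ]
    },
    {
      "tier": "M5",
      "components": ["pg_g_yf", "nucleophile_elbow", "ser_met", "glycine_quad",
                     "aromatic_clamp_1", "catalytic_asp", "catalytic_his",
                     "disulfide_cys", "dxdxr_block"],
      "constraints": [
        {"from": "nucleophile_elbow", "to": "glycine_quad",     "min_sep": 0,  "max_sep": 14},
        {"from": "nucleophile_elbow", "to": "aromatic_clamp_1", "min_sep": 17, "max_sep": 37},
        {"from": "aromatic_clamp_1",  "to": "catalytic_asp",    "min_sep": 9,  "max_sep": 29},
        {"from": "catalytic_asp",     "to": "catalytic_his",    "min_sep": 20, "max_sep": 40},
        {"from": "pg_g_yf",           "to": "nucleophile_elbow","min_sep": 63, "max_sep": 83},
        {"from": "catalytic_his",     "to": "disulfide_cys",    "min_sep": 0,  "max_sep": 15},
        {"from": "disulfide_cys",     "to": "dxdxr_block",      "min_sep": 14, "max_sep": 34}
      ]
    }
  ]
}
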