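Package: petasescan
Title: Motif-Based Screening of PET Hydrolases in Ocean Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for identifying functional polyethylene terephthalate
    hydrolases (PETases) from protein sequences and quantifying them in
    marine metagenomes. Implements a hierarchical five-tier (M1-M5) motif
    classification of candidate dienelactone-hydrolase-domain proteins with
    PROSITE-style patterns and residue distance constraints calibrated on
    the Ideonella sakaiensis PETase reference; a reference-anchored
    key-residue efficiency score with low/medium/high binning; FPKM
    computation with recA single-copy-marker normalization, depth-layer
    summaries and PETase/MHETase co-occurrence; great-circle matching of
    plastic-survey records to sequencing samples with Mann-Whitney
    presence/absence and linear-relationship statistics; and seeded
    synthetic-data generators (planted-motif protein sets and simulated
    plastic surveys) for ground-truthed testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    lme4,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
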