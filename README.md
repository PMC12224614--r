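# petasescan

Motif-based screening of PET hydrolases (PETases) in ocean metagenomes.

## What problem this solves

PET hydrolases — the enzymes that cleave polyethylene terephthalate into
BHET/MHET/TPA — share their α/β-hydrolase fold (the dienelactone hydrolase
domain, Pfam PF01738) with tens of thousands of enzymes that cannot touch
PET.  Screening metagenomes for the domain alone massively overcalls
"PETases".  `petasescan` is for microbial ecologists and enzyme hunters who
need to:

1. **classify** candidate DLH-domain proteins into a cumulative five-tier
   motif ladder **M1–M5** — only a complete M5 (catalytic Ser–Asp–His
   triad, Ser–Met oxyanion hole, `GGGG` helix anchor, two aromatic clamps
   `[PG]-G-[YF]` and the W185 signature, the `DxDxR(Y)xxFxC` packing block
   and the stabilizing disulfide cysteine, all at calibrated residue
   distances) marks a plausible *functional* PETase;
2. **score** candidates for theoretical degradation efficiency against the
   *Ideonella sakaiensis* PETase reference — the weighted count of
   activity-enhancing minus activity-inhibiting key-residue substitutions
   (triad/disulfide positions weigh 3, deletions of them −3), binned
   low (< 4) / medium (4–8) / high (≥ 9);
3. **quantify** variants across samples: FPKM, normalization by the
   single-copy marker *recA* (`Σ FPKM(variants) / Σ FPKM(recA)`),
   depth-layer summaries, mixed-model depth trends, PETase/MHETase
   co-occurrence;
4. **associate** abundance with surface plastic pollution: great-circle
   matching of plastic-survey records (5° radius, samples ≤ 10 m),
   Mann–Whitney presence/absence contrast and an OLS linear fit;
5. **simulate** all of the above: seeded generators for planted-motif
   protein sets (with single-violation decoys) and plastic surveys with a
   known multiplicative effect — every pipeline stage is testable against
   exact ground truth.

## Worked example

```r
library(petasescan)

defs <- load_definitions()                 # bundled M1-M5 definitions
classify_tier(petase_reference(), defs, id = "IsPETase")
#> <tier_classification> IsPETase: M5
#>   pg_g_yf              85-87   PGY
#>   nucleophile_elbow   158-162  GWSMG
#>   ser_met             160-161  SM
#>   glycine_quad        162-165  GGGG
#>   aromatic_clamp_1    185-188  WDSS
#>   catalytic_asp       204-207  ENDS
#>   catalytic_his       234-238  GGSHS
#>   disulfide_cys       239-242  CANS
#>   dxdxr_block         263-273  DNDTRYSTFAC
```

The reference hits M5 with every component at its calibrated anchor
(1-based coordinates; the catalytic serine is position 160).  A 75-candidate
panel with a planted catalog composition is recovered exactly, and an
efficiency panel reproduces the expected top band:

```r
gs <- gen_sequences(sequence_gen_spec(
  n = c(M1 = 4, M2 = 3, M3 = 16, M4 = 29, M5 = 23), seed = 1))
batch_classify(gs$sequences, defs)
#> <tier_table> 75 sequences
#>   tiers: M0:0  M1:4  M2:3  M3:16  M4:29  M5:23

sc <- score_fasta(gen_efficiency_panel(seed = 1)$sequences)
max(sc$raw)          #> 11   (bin "high": 11 enhancing substitutions)
```

A simulated plastic survey stated at the published group structure
(816 matched records, 283 plastic-free vs 533 plastic-positive, group
means 0.0021 / 0.028) runs through the full association pipeline:

```r
sv <- gen_survey(survey_gen_spec(effect = 0.028 / 0.0021, seed = 1))
pa <- plastic_association(sv$plastic, sv$samples, sv$abundance)
nrow(pa$associations)                     #> 816
#> absence:  0.0019 +/- 0.0002 (n=283)
#> presence: 0.0227 +/- 0.0024 (n=533)
#> Mann-Whitney p = 3.5e-50; OLS slope p = 4.7e-45
```

The ~12-fold contrast between the groups and the overwhelming Mann–Whitney
p-value recover the planted presence effect; the weak positive linear
relation with concentration carries a planted population R² of 0.09 (its
single-draw estimate is heavy-tail unstable — see the methods vignette).

A command-line interface wraps the same functions
(`classify`, `score`, `screen`, `abundance`, `assoc`, `simulate`):

```sh
Rscript inst/exec/petasescan classify --fasta candidates.faa --out report.tsv
```

## Acceptance script

`scripts/acceptance.R` re-runs the three headline computations from scratch
— panel classification, panel scoring, and the full survey→matching→
statistics pipeline — on inputs generated at the given seed, logging the
recovered histogram, top score and association statistics, and writes the
target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

* `R/` — motif engine (PROSITE-style compiler/scanner/classifier),
  efficiency scoring, screening orchestration (hmmsearch domtblout and
  SignalP parsers), abundance, plastic association, synthetic generators,
  CLI.
* `inst/extdata/` — *Is*PETase reference, default motif definitions
  (JSON), the stand-in efficiency rules table (synthetic; see the
  vignette).
* `vignettes/petasescan-methods.Rmd` — the model, its assumptions, every
  numerical choice and its rationale, and what a green test does and does
  not establish.
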