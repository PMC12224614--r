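defs <- load_definitions()
ref <- petase_reference()

test_that("PROSITE pattern compiler handles sets, wildcards, quantifiers and errors", {
  p <- compile_pattern("[PG]-G-[YF]")
  expect_length(p$elements, 3)
  expect_setequal(p$elements[[1]]$set, c("P", "G"))
  q <- compile_pattern("D-x-D-x-R-x(2,3)-F-x-C")
  expect_equal(q$elements[[6]]$min, 2L)
  expect_equal(q$elements[[6]]$max, 3L)
  expect_null(q$elements[[2]]$set)
  # excluded sets
  expect_false("P" %in% compile_pattern("{P}")$elements[[1]]$set)
  # malformed patterns name the component
  expect_error(compile_pattern("G-[", component = "glycine_quad"),
               "glycine_quad")
  expect_error(compile_pattern("G--G"), "empty element")
  expect_error(compile_pattern("[B]"), "outside the standard alphabet")
  expect_error(compile_pattern("x(3,1)"), "quantifier")
})

test_that("definitions round-trip through serialization and reject non-cumulative tiers", {
  tmp <- tempfile(fileext = ".json")
  write_definitions(defs, tmp)
  expect_identical(load_definitions(tmp), defs)
  # break cumulativity: drop an M1 component from M2
  doc <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  doc$tiers[[2]]$components <- list("glycine_quad", "aromatic_clamp_1",
                                    "catalytic_asp")
  tmp2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp2, auto_unbox = TRUE)
  expect_error(load_definitions(tmp2), "cumulative")
  expect_error(load_definitions("/nonexistent/defs.json"), "not found")
})

test_that("scan_components enumerates all (overlapping) occurrences deterministically", {
  m <- scan_components("AAGGGGAA", defs$components["glycine_quad"])
  expect_equal(nrow(m), 1)
  expect_equal(m$start + 1L, 3L)   # 1-based positions 3-6
  expect_equal(m$end, 6L)
  expect_equal(m$matched_text, "GGGG")
  m2 <- scan_components("GGGGG", defs$components["glycine_quad"])
  expect_equal(m2$start, c(0L, 1L))
  # matched_text equals the slice (invariant)
  s <- unname(ref)
  all_m <- scan_components(s, defs$components)
  expect_true(all(substring(s, all_m$start + 1L, all_m$end) ==
                    all_m$matched_text))
  # deterministic order
  expect_identical(all_m, all_m[order(all_m$start, all_m$component,
                                      all_m$end), ])
})

test_that("scanner agrees with a naive position-by-position oracle on random sequences", {
  set.seed(101)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    s <- paste(sample(aa, 300, TRUE), collapse = "")
    got <- scan_components(s, defs$components)[, c("component", "start", "end")]
    want <- naive_scan_all(s, defs)
    got <- got[order(got$component, got$start, got$end), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("sequence", i))
  }
})

test_that("classify_tier awards the calibrated reference M5 and degenerate inputs M0", {
  cl <- classify_tier(ref, defs, id = "IsPETase")
  expect_equal(as.character(cl$tier), "M5")
  expect_true(is.na(cl$failed_at))
  # witness placements sit at the calibrated reference anchors
  p <- cl$placements
  expect_equal(p$start[p$component == "nucleophile_elbow"] + 1L, 158L)
  expect_equal(p$start[p$component == "ser_met"] + 1L, 160L)
  expect_equal(p$start[p$component == "dxdxr_block"] + 1L, 263L)
  expect_equal(as.character(classify_tier(strrep("A", 300), defs)$tier), "M0")
  expect_equal(as.character(classify_tier("GWS", defs)$tier), "M0")  # short
  expect_error(classify_tier("GWSMGB", defs), "alphabet")
})

test_that("the ambiguity residue X never satisfies a specific requirement", {
  # X at the catalytic serine breaks the elbow even though x-wildcards accept X
  s <- unname(ref)
  sx <- paste0(substr(s, 1, 159), "X", substr(s, 161, nchar(s)))
  clx <- classify_tier(sx, defs)
  expect_true(as.character(clx$tier) != "M5")
  # but X at a wildcard position is harmless: mutate position 159 (elbow x)
  sw <- paste0(substr(s, 1, 158), "X", substr(s, 160, nchar(s)))
  expect_equal(as.character(classify_tier(sw, defs)$tier), "M5")
})

test_that("single-violation decoys drop exactly one tier", {
  # Ser followed by Leu instead of Met: all other M5 features intact -> M4
  s <- unname(ref)
  s_leu <- paste0(substr(s, 1, 160), "L", substr(s, 162, nchar(s)))
  cl <- classify_tier(s_leu, defs)
  expect_equal(as.character(cl$tier), "M4")
  expect_match(cl$failed_at, "ser_met")
})

test_that("batch_classify preserves order, deduplicates ids and flags bad records", {
  gs <- gen_sequences(sequence_gen_spec(n = c(M1 = 2, M5 = 2), seed = 31))
  tt <- batch_classify(gs$sequences, defs)
  expect_equal(tt$sequence_id, gs$truth$sequence_id)
  expect_equal(as.character(tt$tier), gs$truth$tier)
  # empty input
  empty <- batch_classify(character(0), defs)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(tier_histogram(empty)), 0)
  # duplicate ids
  dup <- stats::setNames(c("AAGGGGAA", "AAGGGGAA"), c("a", "a"))
  expect_warning(td <- batch_classify(dup, defs), "duplicate")
  expect_equal(td$sequence_id, c("a", "a.1"))
  # unreadable record flagged, processing continues
  mix <- stats::setNames(c("AAGGGG", "AAB?", unname(ref)), c("ok", "bad", "ref"))
  expect_warning(tm <- batch_classify(mix, defs))
  expect_true(is.na(tm$tier[2]))
  expect_equal(as.character(tm$tier[3]), "M5")
  expect_equal(nrow(tm), 3)
})

test_that("classification tables report 1-based coordinates and export cleanly", {
  tt <- batch_classify(stats::setNames(unname(ref), "IsPETase"), defs)
  tab <- classification_table(tt)
  expect_named(tab, c("sequence_id", "tier", "component", "start_1based",
                      "end_1based", "matched_text"))
  expect_equal(tab$start_1based[tab$component == "pg_g_yf"], 85L)
  tmp <- tempfile(fileext = ".tsv")
  write_tsv_report(tt, tmp, comments = "toy run")
  lines <- readLines(tmp)
  expect_match(lines[1], "^# toy run")
  re <- utils::read.table(tmp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(re), nrow(tab))
})

test_that("classifier agrees with the exhaustive placement oracle and satisfaction is cumulative", {
  set.seed(77)
  tiers5 <- c("M1", "M2", "M3", "M4", "M5")
  cases <- character(0)
  for (tier in tiers5)
    cases <- c(cases, gen_sequences(sequence_gen_spec(
      n = stats::setNames(3L, tier), length_range = c(250, 300),
      seed = 1000 + match(tier, tiers5)))$sequences)
  for (i in 1:10)
    cases <- c(cases, paste(sample(c("A","C","D","E","F","G","H","S","W","Y","M","N","R","T"),
                                   280, TRUE), collapse = ""))
  for (s in cases) {
    want <- brute_classify(s, defs)
    got <- as.character(classify_tier(s, defs)$tier)
    expect_equal(got, want$tier)
    # cumulativity: satisfaction is monotone down the tier ladder
    k <- match(want$tier, c("M0","M1","M2","M3","M4","M5")) - 1L
    expect_equal(unname(want$satisfied), seq_along(want$satisfied) <= k)
  }
})

test_that("flanking runs of a residue absent from all component alphabets never change the tier", {
  gs <- gen_sequences(sequence_gen_spec(n = c(M2 = 1, M4 = 1, M5 = 1),
                                        seed = 9))
  for (i in seq_along(gs$sequences)) {
    s <- gs$sequences[[i]]
    padded <- paste0(strrep("I", 25), s, strrep("I", 25))
    expect_equal(as.character(classify_tier(padded, defs)$tier),
                 gs$truth$tier[i])
  }
})

test_that("identical input and definitions yield byte-identical output tables", {
  gs <- gen_sequences(sequence_gen_spec(n = c(M3 = 3, M5 = 2), seed = 12))
  t1 <- tempfile(); t2 <- tempfile()
  write_tsv_report(batch_classify(gs$sequences, defs), t1)
  write_tsv_report(batch_classify(gs$sequences, load_definitions()), t2)
  expect_identical(readLines(t1), readLines(t2))
})
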