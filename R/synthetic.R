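# Run code with a local, restorable RNG state so generators never disturb
# the caller's random stream: all randomness flows from the explicit seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the planted-motif sequence generator
#'
#' @param n named integer vector of sequences per tier, e.g.
#'   `c(M1 = 4, M5 = 23)`; tiers M1..M5 (M0 sequences are plain
#'   backgrounds).
#' @param length_range backbone length range (min, max) in residues; must
#'   accommodate the planted span for tiers >= M1.
#' @param background `"uniform"` over the 20 standard residues, or
#'   `"reference"` (residue frequencies of the *Is*PETase reference).
#' @param decoy optional single-violation decoy mode, one of
#'   `"ser_met"`, `"disulfide_cys"`, `"dxdxr_block"`, `"distance"`; decoys
#'   carry a full M5-like layout with exactly that requirement violated
#'   (truth tier M4).
#' @param n_decoy number of decoy sequences.
#' @param seed integer seed; all randomness flows from it.
#' @return a `sequence_gen_spec` list.
#' @export
sequence_gen_spec <- function(n = c(M5 = 10), length_range = c(250, 320),
                              background = c("uniform", "reference"),
                              decoy = NULL, n_decoy = 0L, seed = 1L) {
  background <- match.arg(background)
  if (is.null(names(n)) || !all(names(n) %in% paste0("M", 0:5)))
    stop("n must be named with tiers M0..M5", call. = FALSE)
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  if (!is.null(decoy))
    decoy <- match.arg(decoy, c("ser_met", "disulfide_cys", "dxdxr_block",
                                "distance"))
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be c(min, max)", call. = FALSE)
  structure(list(n = n, length_range = as.integer(length_range),
                 background = background, decoy = decoy,
                 n_decoy = as.integer(n_decoy), seed = as.integer(seed)),
            class = "sequence_gen_spec")
}

# One planted layout: blocks of literal residues at jittered anchor
# separations that satisfy the default distance constraints.  Returns the
# block strings, their 0-based offsets relative to the layout start, and the
# expected component placements (0-based half-open).
planted_layout <- function(tier, decoy = NULL, jitter = TRUE) {
  jit <- function(lo, hi) if (jitter) sample(lo:hi, 1L) else (lo + hi) %/% 2L
  x1 <- sample(setdiff(AA_STANDARD, c("G")), 1L)          # elbow wildcard 1
  x3 <- if (identical(tier, "M5") && !identical(decoy, "ser_met")) "M"
        else sample(setdiff(AA_STANDARD, c("M", "G")), 1L) # elbow wildcard 2
  sep_pg <- jit(68, 78)    # pg_g_yf -> elbow       (ref 73, bounds 63..83)
  sep_cl <- jit(22, 32)    # elbow -> clamp          (ref 27, bounds 17..37)
  sep_as <- jit(14, 24)    # clamp -> asp            (ref 19, bounds  9..29)
  sep_hi <- jit(25, 35)    # asp -> his              (ref 30, bounds 20..40)
  sep_dx <- if (identical(decoy, "distance")) 45L
            else jit(19, 29)  # discys -> dxdxr      (ref 24, bounds 14..34)
  m5ish <- tier == "M5" || !is.null(decoy)
  blocks <- list(); expected <- list()
  add <- function(off, txt) blocks[[length(blocks) + 1L]] <<-
    list(off = off, txt = txt)
  exp_add <- function(comp, off, len) expected[[length(expected) + 1L]] <<-
    data.frame(component = comp, start = off, end = off + len)
  a_el <- 0L
  if (tier %in% c("M4", "M5") || m5ish) {
    a_el <- sep_pg
    add(0L, "PGY"); exp_add("pg_g_yf", 0L, 3L)
  }
  elbow <- paste0("G", x1, "S", x3, "G")
  if (tier %in% c("M2", "M3", "M4", "M5") || m5ish) {
    add(a_el, paste0(elbow, "GGG"))                 # elbow + glycine quad
    exp_add("nucleophile_elbow", a_el, 5L)
    exp_add("glycine_quad", a_el + 4L, 4L)
    if (x3 == "M") exp_add("ser_met", a_el + 2L, 2L)
    a_cl <- a_el + sep_cl
    add(a_cl, "WDSS"); exp_add("aromatic_clamp_1", a_cl, 4L)
    a_as <- a_cl + sep_as
    add(a_as, "ENDS"); exp_add("catalytic_asp", a_as, 4L)
  } else if (tier == "M1") {
    add(a_el, elbow); exp_add("nucleophile_elbow", a_el, 5L)
  }
  if (tier %in% c("M3", "M4", "M5") || m5ish) {
    a_hi <- a_as <- a_el + sep_cl + sep_as
    a_hi <- a_as + sep_hi
    if (m5ish && !identical(decoy, "disulfide_cys")) {
      add(a_hi, "GGSHSCANS")
      exp_add("catalytic_his", a_hi, 5L)
      exp_add("disulfide_cys", a_hi + 5L, 4L)
    } else if (m5ish) {                              # disulfide decoy
      add(a_hi, "GGSHSCATS")
      exp_add("catalytic_his", a_hi, 5L)
    } else {
      add(a_hi, "GGSHS")
      exp_add("catalytic_his", a_hi, 5L)
    }
    if (m5ish) {
      a_dx <- a_hi + 5L + sep_dx
      if (identical(decoy, "dxdxr_block")) {
        add(a_dx, "DNDTKYSTFAC")                     # R -> K kills the block
      } else {
        add(a_dx, "DNDTRYSTFAC")
        exp_add("dxdxr_block", a_dx, 11L)
      }
    }
  }
  span <- max(vapply(blocks, function(b) b$off + nchar(b$txt), integer(1)))
  list(blocks = blocks,
       expected = do.call(rbind, expected),
       span = span)
}

# Background residue sampler.
background_sampler <- function(background) {
  if (background == "uniform") {
    function(k) sample(AA_STANDARD, k, replace = TRUE)
  } else {
    ref <- strsplit(unname(petase_reference()), "")[[1]]
    tab <- table(factor(ref, levels = AA_STANDARD))
    pr <- as.numeric(tab) / sum(tab)
    function(k) sample(AA_STANDARD, k, replace = TRUE, prob = pr)
  }
}

#' Generate planted-motif protein sequences with ground truth
#'
#' Builds random protein backbones with motif components planted at
#' constraint-satisfying offsets (jittered within the default distance
#' bounds).  Backbones are rejection-sampled: any sequence in which a
#' component matches outside its planted site - or an unplanted component
#' matches at all - is regenerated, so truth labels are exact by
#' construction.  Decoy mode plants a full M5-like layout violating exactly
#' one named requirement (truth tier M4).
#'
#' @param spec a [sequence_gen_spec()].
#' @param defs motif definitions used for the rejection scan (default
#'   bundled).
#' @return object of class `planted_sequences`: list with `sequences`
#'   (named character vector) and `truth` (data.frame: `sequence_id`,
#'   `tier`, `decoy`).
#' @examples
#' gs <- gen_sequences(sequence_gen_spec(n = c(M5 = 2), seed = 7))
#' gs$truth
#' @export
gen_sequences <- function(spec, defs = load_definitions()) {
  stopifnot(inherits(spec, "sequence_gen_spec"))
  draw_bg <- background_sampler(spec$background)
  comps <- defs$components
  make_one <- function(tier, decoy) {
    for (try in 1:200) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      if (tier == "M0" && is.null(decoy)) {
        chars <- draw_bg(L)
        lay <- list(expected = NULL)
        off0 <- 0L
      } else {
        lay <- planted_layout(tier, decoy)
        if (lay$span + 2L > L)
          stop("length_range too short for tier ", tier,
               " (planted span ", lay$span, ")", call. = FALSE)
        off0 <- sample(1L:(L - lay$span - 1L), 1L)
        chars <- draw_bg(L)
        for (b in lay$blocks) {
          txt <- strsplit(b$txt, "")[[1]]
          chars[(off0 + b$off + 1L):(off0 + b$off + length(txt))] <- txt
        }
      }
      got <- scan_components(paste(chars, collapse = ""), comps)
      want <- lay$expected
      if (is.null(want)) {
        if (!nrow(got)) return(paste(chars, collapse = ""))
      } else {
        want$start <- want$start + off0
        want$end <- want$end + off0
        key <- function(d) sort(paste(d$component, d$start, d$end))
        if (identical(key(got), key(want)))
          return(paste(chars, collapse = ""))
      }
    }
    stop("rejection sampling failed for tier ", tier,
         " after 200 attempts", call. = FALSE)
  }
  with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0)
    tiers <- character(0); decoys <- character(0)
    for (tier in names(spec$n)) {
      for (i in seq_len(spec$n[[tier]])) {
        ids <- c(ids, sprintf("%s_%03d", tier, i))
        seqs <- c(seqs, make_one(tier, NULL))
        tiers <- c(tiers, tier); decoys <- c(decoys, NA_character_)
      }
    }
    if (!is.null(spec$decoy) && spec$n_decoy > 0L) {
      for (i in seq_len(spec$n_decoy)) {
        ids <- c(ids, sprintf("decoy_%s_%03d", spec$decoy, i))
        seqs <- c(seqs, make_one("M5", spec$decoy))
        tiers <- c(tiers, "M4"); decoys <- c(decoys, spec$decoy)
      }
    }
    names(seqs) <- ids
    structure(list(sequences = seqs,
                   truth = data.frame(sequence_id = ids, tier = tiers,
                                      decoy = decoys,
                                      stringsAsFactors = FALSE)),
              class = "planted_sequences")
  })
}

#' @export
print.planted_sequences <- function(x, ...) {
  cat("<planted_sequences> ", length(x$sequences), " sequences: ",
      paste(sprintf("%s:%d", names(table(x$truth$tier)),
                    as.integer(table(x$truth$tier))), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Write planted sequences as FASTA (+ truth table)
#'
#' Deterministic writer (60-column wrapping), so identical generator runs
#' yield byte-identical files.
#'
#' @param x a `planted_sequences` object.
#' @param fasta output FASTA path.
#' @param truth optional output TSV path for the truth table.
#' @return `fasta`, invisibly.
#' @export
write_sequences <- function(x, fasta, truth = NULL) {
  stopifnot(inherits(x, "planted_sequences"))
  con <- file(fasta, open = "wt")
  for (i in seq_along(x$sequences)) {
    writeLines(paste0(">", names(x$sequences)[i]), con)
    s <- x$sequences[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  close(con)
  if (!is.null(truth))
    utils::write.table(x$truth, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta)
}

#' Specification for the simulated plastic survey
#'
#' Defaults state the reference scenario: 816 matched plastic records of
#' which 533 are plastic-positive, a 10-fold multiplicative abundance effect
#' of plastic presence, baseline mean normalized abundance 0.0021, and
#' log-normal noise sigma 1.5 (which reproduces the reference standard
#' errors at these group sizes).  Plastic concentration for
#' positive records is log-normal with sdlog 1.26, chosen so the population
#' R-squared of the linear abundance-concentration relation is 0.09 under
#' these defaults.
#'
#' @param n_matched plastic records with an in-radius surface sample.
#' @param n_unmatched plastic records placed out of reach of any sample
#'   (discarded by matching).
#' @param frac_positive fraction of matched records with plastic detected.
#' @param baseline_mean mean normalized abundance in plastic-free samples.
#' @param effect multiplicative group-mean effect of plastic presence
#'   (>= 1).
#' @param sdlog_noise log-normal noise sigma of the abundance draw.
#' @param conc_meanlog,conc_sdlog log-normal parameters of positive plastic
#'   concentrations (g/km^2).
#' @param n_deep_decoys deep (200 m) samples placed near stations; must be
#'   excluded by the depth filter.
#' @param surface_depth,deep_depth sample depths in meters.
#' @param seed integer seed.
#' @return a `survey_gen_spec` list.
#' @export
survey_gen_spec <- function(n_matched = 816L, n_unmatched = 34L,
                            frac_positive = 533 / 816,
                            baseline_mean = 0.0021, effect = 10,
                            sdlog_noise = 1.5,
                            conc_meanlog = log(500), conc_sdlog = 1.26,
                            n_deep_decoys = 20L,
                            surface_depth = 5, deep_depth = 200,
                            seed = 1L) {
  stopifnot(frac_positive >= 0, frac_positive <= 1, effect >= 1,
            baseline_mean > 0, sdlog_noise >= 0)
  structure(list(n_matched = as.integer(n_matched),
                 n_unmatched = as.integer(n_unmatched),
                 frac_positive = frac_positive,
                 baseline_mean = baseline_mean, effect = effect,
                 sdlog_noise = sdlog_noise, conc_meanlog = conc_meanlog,
                 conc_sdlog = conc_sdlog,
                 n_deep_decoys = as.integer(n_deep_decoys),
                 surface_depth = surface_depth, deep_depth = deep_depth,
                 seed = as.integer(seed)),
            class = "survey_gen_spec")
}

#' Simulate an ocean plastic survey with matched sequencing samples
#'
#' Stations sit on a widely spaced ocean grid (pairwise farther apart than
#' twice the plastic jitter), each matched plastic record is jittered
#' around its own station so the nearest-sample matching ground truth is
#' exact, unmatched records are placed beyond the search radius of every
#' station, and deep decoy samples near stations exercise the depth
#' pre-filter.  Plastic-positive stations draw abundance from
#' `effect x baseline` with multiplicative log-normal noise; in positive
#' records the mean abundance additionally rises linearly with plastic
#' concentration.
#'
#' @param spec a [survey_gen_spec()].
#' @return object of class `survey_sim`: list with `plastic`
#'   (`record_id`, `lat`, `lon`, `concentration`), `samples` (`sample_id`,
#'   `lat`, `lon`, `depth`), `abundance` (`sample_id`, `value`), and
#'   `truth` (generating parameters, matched/positive ids, expected group
#'   means).
#' @export
gen_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_gen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_matched
    grid <- expand.grid(lat = seq(-57, 57, by = 2),
                        lon = seq(-178, 178, by = 4))
    if (n + 0L > nrow(grid))
      stop("n_matched exceeds available station grid", call. = FALSE)
    cells <- grid[sample.int(nrow(grid), n), ]
    st_lat <- cells$lat + runif(n, -0.2, 0.2)
    st_lon <- cells$lon + runif(n, -0.2, 0.2)
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      lat = st_lat, lon = st_lon, depth = spec$surface_depth,
      stringsAsFactors = FALSE)
    # plastic records jittered around their own station
    pl_lat <- st_lat + runif(n, -0.3, 0.3)
    pl_lon <- st_lon + runif(n, -0.3, 0.3)
    n_pos <- round(spec$frac_positive * n)
    pos <- sort(sample.int(n, n_pos))
    conc <- numeric(n)
    conc[pos] <- rlnorm(n_pos, spec$conc_meanlog, spec$conc_sdlog)
    plastic <- data.frame(
      record_id = sprintf("P%04d", seq_len(n)),
      lat = pl_lat, lon = pl_lon, concentration = conc,
      stringsAsFactors = FALSE)
    # out-of-reach plastic records (discarded by matching)
    if (spec$n_unmatched > 0L) {
      plastic <- rbind(plastic, data.frame(
        record_id = sprintf("PX%04d", seq_len(spec$n_unmatched)),
        lat = runif(spec$n_unmatched, 68, 80),
        lon = runif(spec$n_unmatched, -170, 170),
        concentration = rlnorm(spec$n_unmatched, spec$conc_meanlog,
                               spec$conc_sdlog),
        stringsAsFactors = FALSE))
    }
    # abundance: baseline for plastic-free, linear-in-concentration mean
    # for plastic-positive, multiplicative log-normal noise throughout
    mean_pos <- spec$effect * spec$baseline_mean
    beta <- if (n_pos > 0)
      (mean_pos - spec$baseline_mean) / mean(conc[pos]) else 0
    mu <- spec$baseline_mean + beta * conc
    s <- spec$sdlog_noise
    value <- mu * exp(rnorm(n, 0, s) - s^2 / 2)
    abundance <- data.frame(sample_id = samples$sample_id, value = value,
                            stringsAsFactors = FALSE)
    # deep decoy samples near the first stations: excluded by depth filter
    if (spec$n_deep_decoys > 0L) {
      k <- seq_len(min(spec$n_deep_decoys, n))
      deep <- data.frame(
        sample_id = sprintf("D%04d", k),
        lat = st_lat[k] + 0.05, lon = st_lon[k] + 0.05,
        depth = spec$deep_depth, stringsAsFactors = FALSE)
      samples <- rbind(samples, deep)
      abundance <- rbind(abundance, data.frame(
        sample_id = deep$sample_id,
        value = spec$baseline_mean * exp(rnorm(length(k), 0, s) - s^2 / 2),
        stringsAsFactors = FALSE))
    }
    structure(list(plastic = plastic, samples = samples,
                   abundance = abundance,
                   truth = list(n_matched = n, n_positive = n_pos,
                                positive_records = plastic$record_id[pos],
                                beta = beta,
                                mean_presence = mean_pos,
                                mean_absence = spec$baseline_mean,
                                effect = spec$effect),
                   spec = spec),
              class = "survey_sim")
  })
}

#' @export
print.survey_sim <- function(x, ...) {
  cat("<survey_sim> ", nrow(x$plastic), " plastic records, ",
      nrow(x$samples), " samples (", x$truth$n_matched, " matched, ",
      x$truth$n_positive, " plastic-positive)\n", sep = "")
  invisible(x)
}

#' Write a simulated survey to TSV files
#'
#' @param x a `survey_sim` object.
#' @param dir output directory (created if needed); writes `plastic.tsv`,
#'   `samples.tsv`, `abundance.tsv` and `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(x, dir) {
  stopifnot(inherits(x, "survey_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(x$plastic, "plastic.tsv"); wt(x$samples, "samples.tsv")
  wt(x$abundance, "abundance.tsv")
  jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate station depth profiles with a planted depth trend
#'
#' Emulates repeated vertical profiles: log10 normalized abundance rises
#' linearly with depth (km) with a per-station random intercept, matching
#' the [depth_trend()] model.
#'
#' @param n_stations number of stations (default 11).
#' @param depths sampled depths in meters per station.
#' @param slope planted slope per km of depth on the log10 scale.
#' @param intercept log10 abundance at the surface.
#' @param station_sd SD of station random intercepts.
#' @param sigma residual SD on the log10 scale.
#' @param seed integer seed.
#' @return data.frame: `sample_id`, `station`, `depth`, `value`; planted
#'   parameters in `attr(,"truth")`.
#' @export
gen_depth_profiles <- function(n_stations = 11L,
                               depths = c(50, 250, 750, 1500, 2500, 3500),
                               slope = 0.4, intercept = -3,
                               station_sd = 0.3, sigma = 0.35, seed = 1L) {
  with_seed(seed, {
    st <- rep(sprintf("ST%02d", seq_len(n_stations)), each = length(depths))
    dp <- rep(depths, times = n_stations)
    b <- rnorm(n_stations, 0, station_sd)
    y <- intercept + slope * dp / 1000 + b[as.integer(factor(st))] +
      rnorm(length(st), 0, sigma)
    out <- data.frame(sample_id = sprintf("%s_%04dm", st, dp),
                      station = st, depth = dp, value = 10^y,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(slope = slope, intercept = intercept,
                               station_sd = station_sd, sigma = sigma)
    out
  })
}

#' Generate a reference-derived efficiency scoring panel
#'
#' Builds a candidate panel of *Is*PETase point-mutant (and truncation)
#' variants with known raw efficiency scores under the bundled scheme,
#' mirroring the catalog structure reported for ocean candidates: a small
#' high-band group with 9-11 activity-enhancing substitutions (maximum
#' planted score 11), and a majority of low scorers (few or no enhancing
#' substitutions, inhibiting back-wall substitutions, or C-terminal
#' truncations that delete critical residues).
#'
#' @param n_total panel size (default 75).
#' @param n_high number of high-band candidates; their planted scores are
#'   spread over 9..11 with at least one at 11.
#' @param n_truncated number of candidates truncated before the catalytic
#'   His (planted negative scores).
#' @param scheme scoring scheme the panel is built against (default
#'   bundled).
#' @param seed integer seed.
#' @return object of class `efficiency_panel`: list with `sequences`
#'   (named character vector) and `truth` (data.frame: `sequence_id`,
#'   `raw`).
#' @export
gen_efficiency_panel <- function(n_total = 75L, n_high = 8L,
                                 n_truncated = 6L, scheme = load_scheme(),
                                 seed = 1L) {
  stopifnot(n_high + n_truncated <= n_total)
  ref <- unname(petase_reference())
  rules <- scheme$rules
  std <- rules[rules$class == "standard", , drop = FALSE]
  pos_rules <- std[vapply(std$positive, length, integer(1)) > 0, ,
                   drop = FALSE]
  neg_rules <- std[vapply(std$negative, length, integer(1)) > 0, ,
                   drop = FALSE]
  if (nrow(pos_rules) < 11L)
    stop("scheme has fewer than 11 standard rules with positive sets",
         call. = FALSE)
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); raws <- numeric(0)
    # high band: planted scores cycling 11, 10, 9
    high_scores <- rep(c(11L, 10L, 9L), length.out = n_high)
    for (i in seq_len(n_high)) {
      k <- high_scores[i]
      pick <- sample.int(nrow(pos_rules), k)
      chars <- strsplit(ref, "")[[1]]
      for (j in pick)
        chars[pos_rules$position[j]] <- sample(pos_rules$positive[[j]], 1L)
      ids <- c(ids, sprintf("high_%02d", i))
      seqs <- c(seqs, paste(chars, collapse = ""))
      raws <- c(raws, k)
    }
    # truncated: cut before the catalytic His; lose every critical rule
    # at or beyond the cut (planted absence penalties)
    crit <- rules[rules$class != "standard", , drop = FALSE]
    for (i in seq_len(n_truncated)) {
      cut <- 230L
      chars <- strsplit(ref, "")[[1]][seq_len(cut)]
      lost <- sum(crit$position > cut)
      ids <- c(ids, sprintf("trunc_%02d", i))
      seqs <- c(seqs, paste(chars, collapse = ""))
      raws <- c(raws, lost * scheme$weights$absence_penalty_critical)
    }
    # remainder: 0-3 enhancing substitutions, sometimes one inhibiting
    n_rest <- n_total - n_high - n_truncated
    for (i in seq_len(n_rest)) {
      k <- sample(0:3, 1L)
      raw <- k
      chars <- strsplit(ref, "")[[1]]
      if (k > 0) {
        pick <- sample.int(nrow(pos_rules), k)
        for (j in pick)
          chars[pos_rules$position[j]] <- sample(pos_rules$positive[[j]], 1L)
      }
      if (i %% 4L == 0L && nrow(neg_rules)) {
        j <- sample.int(nrow(neg_rules), 1L)
        chars[neg_rules$position[j]] <- sample(neg_rules$negative[[j]], 1L)
        raw <- raw - 1L
      }
      ids <- c(ids, sprintf("low_%02d", i))
      seqs <- c(seqs, paste(chars, collapse = ""))
      raws <- c(raws, raw)
    }
    names(seqs) <- ids
    structure(list(sequences = seqs,
                   truth = data.frame(sequence_id = ids, raw = raws,
                                      stringsAsFactors = FALSE)),
              class = "efficiency_panel")
  })
}
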