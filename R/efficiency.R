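#' Load a key-residue scoring scheme
#'
#' Reads a scoring scheme (JSON) of key-residue rules in *Is*PETase 1-based
#' numbering.  With `config = NULL` the bundled stand-in table is returned
#' (see `inst/extdata/efficiency_rules_synthetic.json`): catalytic-triad and
#' disulfide positions as critical rules, plus standard rules carrying
#' published activity-enhancing or -inhibiting substitutions.
#'
#' @param config path to a JSON scheme, or `NULL` for the bundled default.
#' @return an object of class `scoring_scheme`: list with `rules`
#'   (data.frame: `position`, `reference_residue`, `positive`, `negative`
#'   (list columns), `class`), `weights` and `thresholds`.
#' @export
load_scheme <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "efficiency_rules_synthetic.json",
                          package = "petasescan", mustWork = TRUE)
  doc <- jsonlite::read_json(config, simplifyVector = FALSE)
  w <- doc$weights
  weights <- list(
    standard = if (is.null(w$standard)) 1 else as.numeric(w$standard),
    critical = if (is.null(w$critical)) 3 else as.numeric(w$critical),
    absence_penalty_critical = if (is.null(w$absence_penalty_critical)) -3
                               else as.numeric(w$absence_penalty_critical))
  if (!(weights$critical >= weights$standard && weights$standard > 0))
    stop("scheme weights must satisfy critical >= standard > 0",
         call. = FALSE)
  th <- doc$thresholds
  thresholds <- c(medium = if (is.null(th$medium)) 4 else as.numeric(th$medium),
                  high = if (is.null(th$high)) 9 else as.numeric(th$high))
  if (thresholds[["medium"]] > thresholds[["high"]])
    stop("unordered bin thresholds: need medium <= high", call. = FALSE)
  rules <- do.call(rbind, lapply(doc$rules, function(r) {
    stopifnot(!is.null(r$position), !is.null(r$reference_residue))
    data.frame(position = as.integer(r$position),
               reference_residue = r$reference_residue,
               class = if (is.null(r$class)) "standard" else r$class,
               stringsAsFactors = FALSE)
  }))
  rules$positive <- lapply(doc$rules, function(r) as.character(unlist(r$positive)))
  rules$negative <- lapply(doc$rules, function(r) as.character(unlist(r$negative)))
  for (i in seq_len(nrow(rules))) {
    ov <- intersect(setdiff(rules$positive[[i]], "*"),
                    setdiff(rules$negative[[i]], "*"))
    if (length(ov))
      stop("rule at position ", rules$position[i],
           ": positive and negative sets overlap (",
           paste(ov, collapse = ","), ")", call. = FALSE)
  }
  if (!all(rules$class %in% c("standard", "catalytic_triad", "disulfide")))
    stop("rule class must be standard, catalytic_triad or disulfide",
         call. = FALSE)
  structure(list(rules = rules, weights = weights, thresholds = thresholds),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", nrow(x$rules), " rules (",
      sum(x$rules$class != "standard"), " critical); weights ",
      x$weights$standard, "/", x$weights$critical,
      ", absence penalty ", x$weights$absence_penalty_critical,
      "; bins low<", x$thresholds[["medium"]], " medium<",
      x$thresholds[["high"]], " high\n", sep = "")
  invisible(x)
}

#' Globally align a candidate to the *Is*PETase reference
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 11,
#' extend 1, as in the classic protein-alignment defaults) used to map
#' candidate residues onto reference numbering.  Traceback tie-breaking is
#' delegated to the deterministic Biostrings implementation.
#'
#' @param candidate amino-acid string.
#' @param reference amino-acid string (default: bundled *Is*PETase).
#' @param gap_opening,gap_extension affine gap costs.
#' @return object of class `reference_alignment`: list with `columns`
#'   (data.frame: `ref_pos`, `cand_pos` (NA at gaps, both 1-based),
#'   `ref_char`, `cand_char`), `score`, `candidate_id`.
#' @export
align_to_reference <- function(candidate, reference = petase_reference(),
                               gap_opening = 11, gap_extension = 1) {
  if (!nzchar(candidate) || !nzchar(reference))
    stop("candidate and reference must be non-empty", call. = FALSE)
  cand_id <- if (!is.null(names(candidate))) names(candidate)[1] else "<candidate>"
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(reference[[1]])),
    subject = Biostrings::AAString(toupper(candidate[[1]])),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  rc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  cc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- ifelse(rc == "-", NA_integer_, cumsum(rc != "-"))
  cand_pos <- ifelse(cc == "-", NA_integer_, cumsum(cc != "-"))
  structure(list(
    candidate_id = cand_id,
    columns = data.frame(ref_pos = ref_pos, cand_pos = cand_pos,
                         ref_char = rc, cand_char = cc,
                         stringsAsFactors = FALSE),
    score = Biostrings::score(aln)),
    class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat(sprintf("<reference_alignment> %s: %d columns, score %.1f\n",
              x$candidate_id, nrow(x$columns), x$score))
  invisible(x)
}

#' Read candidate residues at the scheme's key positions
#'
#' For each rule, reports the candidate residue aligned to the rule's
#' reference position, or `NA` ("absent") when the position is aligned to a
#' gap.
#'
#' @param alignment a `reference_alignment`.
#' @param scheme a `scoring_scheme`.
#' @return data.frame: `position`, `reference_residue`, `class`, `observed`
#'   (NA when absent).
#' @export
extract_key_residues <- function(alignment, scheme) {
  stopifnot(inherits(alignment, "reference_alignment"),
            inherits(scheme, "scoring_scheme"))
  cols <- alignment$columns
  ref_len <- max(cols$ref_pos, na.rm = TRUE)
  if (any(scheme$rules$position > ref_len))
    stop("scheme error: rule position beyond reference length (", ref_len,
         ")", call. = FALSE)
  observed <- vapply(scheme$rules$position, function(p) {
    i <- which(cols$ref_pos == p)
    ch <- cols$cand_char[i]
    if (ch == "-") NA_character_ else ch
  }, character(1))
  data.frame(position = scheme$rules$position,
             reference_residue = scheme$rules$reference_residue,
             class = scheme$rules$class,
             observed = observed, stringsAsFactors = FALSE)
}

#' Score observed key residues
#'
#' Per rule: `+weight` when the observed residue is in the rule's positive
#' (activity-enhancing) set, `-weight` when in the negative (inhibiting)
#' set (`"*"` in a set means every non-reference residue), the critical
#' absence penalty when the position is deleted in a critical rule, else 0.
#' Standard rules weigh `weights$standard`, catalytic-triad and disulfide
#' rules `weights$critical`.  The raw score is the sum; bins are assigned by
#' [bin_efficiency()].
#'
#' @param observed data.frame from [extract_key_residues()].
#' @param scheme a `scoring_scheme`.
#' @return object of class `efficiency_score`: list with `raw`,
#'   `n_positive`, `n_negative`, `per_rule` (data.frame with
#'   `contribution`), `bin`.
#' @export
score_efficiency <- function(observed, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  w <- scheme$weights
  per <- observed
  contrib <- numeric(nrow(per))
  kind <- character(nrow(per))
  for (i in seq_len(nrow(per))) {
    critical <- per$class[i] != "standard"
    weight <- if (critical) w$critical else w$standard
    obs <- per$observed[i]
    pos <- scheme$rules$positive[[i]]
    neg <- scheme$rules$negative[[i]]
    if (is.na(obs)) {
      contrib[i] <- if (critical) w$absence_penalty_critical else 0
      kind[i] <- if (critical) "absent_critical" else "absent"
    } else if (obs == per$reference_residue[i]) {
      contrib[i] <- 0; kind[i] <- "reference"
    } else if (obs %in% pos || ("*" %in% pos)) {
      contrib[i] <- weight; kind[i] <- "positive"
    } else if (obs %in% neg || ("*" %in% neg)) {
      contrib[i] <- -weight; kind[i] <- "negative"
    } else {
      contrib[i] <- 0; kind[i] <- "neutral"
    }
  }
  per$contribution <- contrib
  per$kind <- kind
  raw <- sum(contrib)
  structure(list(raw = raw,
                 n_positive = sum(kind == "positive"),
                 n_negative = sum(kind == "negative"),
                 per_rule = per,
                 bin = bin_efficiency(raw, scheme$thresholds)),
            class = "efficiency_score")
}

#' @export
print.efficiency_score <- function(x, ...) {
  cat(sprintf("<efficiency_score> raw %g (%d positive, %d negative): %s\n",
              x$raw, x$n_positive, x$n_negative, x$bin))
  invisible(x)
}

#' Bin a raw efficiency score into low / medium / high
#'
#' Piecewise-constant mapping with boundaries inclusive on the upper bin:
#' `raw >= thresholds["high"]` is high, `raw >= thresholds["medium"]` is
#' medium, otherwise low.  Defaults (medium 4, high 9) anchor the high band
#' at scores of 9 and above and the low band strictly below 4.
#'
#' @param raw numeric raw score(s).
#' @param thresholds named numeric vector `c(medium=, high=)`, ordered.
#' @return character vector of bins.
#' @export
bin_efficiency <- function(raw, thresholds = c(medium = 4, high = 9)) {
  if (!all(c("medium", "high") %in% names(thresholds)) ||
      thresholds[["medium"]] > thresholds[["high"]])
    stop("thresholds must be an ordered c(medium=, high=) pair",
         call. = FALSE)
  ifelse(raw >= thresholds[["high"]], "high",
         ifelse(raw >= thresholds[["medium"]], "medium", "low"))
}

#' Score every sequence of a FASTA against the reference
#'
#' Convenience wrapper: align, extract key residues, score.  The returned
#' table carries one column per critical rule with the observed residue
#' (`pos<position>`).
#'
#' @param fasta FASTA path, `AAStringSet`, or named character vector.
#' @param scheme scoring scheme (default bundled).
#' @param reference reference sequence (default bundled *Is*PETase).
#' @return data.frame: `sequence_id`, `raw`, `n_positive`, `n_negative`,
#'   `bin`, plus observed-residue columns for critical rules.
#' @export
score_fasta <- function(fasta, scheme = load_scheme(),
                        reference = petase_reference()) {
  seqs <- read_protein_fasta(fasta)
  ids <- dedup_ids(names(seqs))
  crit <- scheme$rules$position[scheme$rules$class != "standard"]
  rows <- lapply(seq_along(seqs), function(i) {
    aln <- align_to_reference(seqs[[i]], reference)
    es <- score_efficiency(extract_key_residues(aln, scheme), scheme)
    obs <- es$per_rule$observed[match(crit, es$per_rule$position)]
    row <- data.frame(sequence_id = ids[i], raw = es$raw,
                      n_positive = es$n_positive, n_negative = es$n_negative,
                      bin = es$bin, stringsAsFactors = FALSE)
    for (j in seq_along(crit)) row[[paste0("pos", crit[j])]] <- obs[j]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
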