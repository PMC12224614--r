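TIER_LEVELS <- c("M0", "M1", "M2", "M3", "M4", "M5")

# Split a sequence into a validated character vector of residues.
seq_chars <- function(residues, id = "<sequence>") {
  if (!is.character(residues) || length(residues) != 1L)
    stop("residues must be a character scalar", call. = FALSE)
  chars <- strsplit(toupper(residues), "")[[1]]
  if (!length(chars))
    stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "' contains residue(s) outside the accepted ",
         "alphabet: ", paste(bad, collapse = ","), call. = FALSE)
  chars
}

#' Scan a protein sequence for motif components
#'
#' Enumerates every occurrence of every component pattern, overlapping
#' placements included.  Coordinates are 0-based half-open (`start`,
#' `end`); reporting functions convert to 1-based.
#'
#' @param residues amino-acid string (20 standard letters plus X).
#' @param components named list of compiled components, e.g.
#'   `load_definitions()$components` (or a subset).
#' @param id sequence id used in error messages.
#' @return data.frame with columns `component`, `start`, `end`,
#'   `matched_text`, ordered by `start` then component name.
#' @examples
#' defs <- load_definitions()
#' scan_components("AAGGGGAA", defs$components["glycine_quad"])
#' @export
scan_components <- function(residues, components, id = "<sequence>") {
  chars <- seq_chars(residues, id)
  out <- lapply(names(components), function(nm) {
    m <- pattern_matches(chars, components[[nm]]$pattern)
    if (!nrow(m)) return(NULL)
    m$component <- nm
    m
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(component = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0)))
  out$matched_text <- vapply(seq_len(nrow(out)), function(i)
    paste(chars[(out$start[i] + 1L):out$end[i]], collapse = ""), character(1))
  out <- out[order(out$start, out$component, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("component", "start", "end", "matched_text")]
}

# Find the lexicographically smallest witness placement (by component start,
# in the tier's component order) satisfying all distance constraints of a
# tier, or NULL.  placements: data.frame from scan_components.
find_witness <- function(tier, placements, components) {
  cn <- tier$components
  # candidate starts per component, sorted (lexicographic tie-break)
  plc <- lapply(cn, function(nm) {
    p <- placements[placements$component == nm, , drop = FALSE]
    p[order(p$start, p$end), , drop = FALSE]
  })
  names(plc) <- cn
  if (any(vapply(plc, nrow, integer(1)) == 0L)) return(NULL)
  # constraints indexed by the later-assigned component
  idx <- stats::setNames(seq_along(cn), cn)
  cons_by <- vector("list", length(cn))
  for (dc in tier$constraints) {
    at <- max(idx[[dc$from]], idx[[dc$to]])
    cons_by[[at]] <- c(cons_by[[at]], list(dc))
  }
  # shared-serine rule: ser_met must sit on the nucleophile-elbow serine
  link <- NULL
  if (all(c("ser_met", "nucleophile_elbow") %in% cn)) {
    off_elbow <- components[["nucleophile_elbow"]]$serine_offset
    off_sm <- components[["ser_met"]]$serine_offset
    if (!is.na(off_elbow) && !is.na(off_sm))
      link <- list(at = max(idx[["ser_met"]], idx[["nucleophile_elbow"]]),
                   delta = off_elbow - off_sm)
  }
  assign <- vector("list", length(cn))
  dfs <- function(j) {
    if (j > length(cn)) return(TRUE)
    p <- plc[[j]]
    for (i in seq_len(nrow(p))) {
      assign[[j]] <<- p[i, , drop = FALSE]
      ok <- TRUE
      for (dc in cons_by[[j]]) {
        s_from <- assign[[idx[[dc$from]]]]$start
        s_to <- assign[[idx[[dc$to]]]]$start
        sep <- s_to - s_from
        if (sep < dc$min_sep || sep > dc$max_sep) { ok <- FALSE; break }
      }
      if (ok && !is.null(link) && j == link$at) {
        s_elbow <- assign[[idx[["nucleophile_elbow"]]]]$start
        s_sm <- assign[[idx[["ser_met"]]]]$start
        if (s_sm != s_elbow + link$delta) ok <- FALSE
      }
      if (ok && dfs(j + 1L)) return(TRUE)
    }
    FALSE
  }
  if (!dfs(1L)) return(NULL)
  out <- do.call(rbind, assign)
  out$component <- cn
  rownames(out) <- NULL
  out[, c("component", "start", "end", "matched_text")]
}

# Human-readable reason why `tier` is not satisfied (first unmet requirement).
explain_failure <- function(tier, placements) {
  for (nm in tier$components)
    if (!any(placements$component == nm))
      return(sprintf("%s: no match for component '%s'", tier$tier, nm))
  if (all(c("ser_met", "nucleophile_elbow") %in% tier$components)) {
    s_el <- placements$start[placements$component == "nucleophile_elbow"]
    s_sm <- placements$start[placements$component == "ser_met"]
    if (!any(outer(s_sm, s_el + 2L, `==`)))
      return(sprintf(
        "%s: no ser_met placement shares its serine with the nucleophile_elbow",
        tier$tier))
  }
  for (dc in tier$constraints) {
    s_from <- placements$start[placements$component == dc$from]
    s_to <- placements$start[placements$component == dc$to]
    seps <- as.vector(outer(s_to, s_from, `-`))
    if (!any(seps >= dc$min_sep & seps <= dc$max_sep))
      return(sprintf("%s: no placement of '%s'->'%s' within [%d,%d] residues",
                     tier$tier, dc$from, dc$to, dc$min_sep, dc$max_sep))
  }
  sprintf("%s: no joint placement satisfies all constraints", tier$tier)
}

#' Classify a protein sequence into its highest motif tier
#'
#' Awards the highest tier M1..M5 for which some combination of component
#' placements satisfies every distance constraint (existential semantics);
#' the Ser-Met oxyanion component must share its serine with the nucleophile
#' elbow.  Sequences matching no tier (including sequences shorter than the
#' minimal motif span) are M0.
#'
#' @param residues amino-acid string.
#' @param defs a `motif_definitions` object from [load_definitions()].
#' @param id sequence id.
#' @return an object of class `tier_classification`: list with
#'   `sequence_id`, `tier` (factor M0..M5), `placements` (witness placement
#'   data.frame, 0-based half-open coordinates; `NULL` for M0) and
#'   `failed_at` (why the next tier up is not met; `NA` for M5).
#' @examples
#' defs <- load_definitions()
#' classify_tier(petase_reference(), defs)$tier  # M5
#' @export
classify_tier <- function(residues, defs, id = "<sequence>") {
  stopifnot(inherits(defs, "motif_definitions"))
  placements <- scan_components(residues, defs$components, id = id)
  awarded <- "M0"; witness <- NULL
  for (k in 5:1) {
    w <- find_witness(defs$tiers[[k]], placements, defs$components)
    if (!is.null(w)) { awarded <- defs$tiers[[k]]$tier; witness <- w; break }
  }
  failed_at <- if (awarded == "M5") NA_character_ else
    explain_failure(defs$tiers[[match(awarded, TIER_LEVELS)]], placements)
  structure(list(sequence_id = id,
                 tier = factor(awarded, levels = TIER_LEVELS),
                 placements = witness,
                 failed_at = failed_at),
            class = "tier_classification")
}

#' @export
print.tier_classification <- function(x, ...) {
  cat(sprintf("<tier_classification> %s: %s\n", x$sequence_id,
              as.character(x$tier)))
  if (!is.null(x$placements)) {
    p <- x$placements
    cat(sprintf("  %-18s %4d-%-4d %s\n", p$component, p$start + 1L, p$end,
                p$matched_text), sep = "")
  }
  if (!is.na(x$failed_at)) cat("  next tier fails at:", x$failed_at, "\n")
  invisible(x)
}

#' Classify all sequences of a FASTA file or set
#'
#' One classification per record, input order preserved.  Duplicate sequence
#' ids are suffix-deduplicated with a warning; records that cannot be
#' classified (e.g. residues outside the alphabet) are flagged with tier `NA`
#' and processing continues.
#'
#' @param fasta path to a (multi-record, line-wrapped) FASTA file, an
#'   `AAStringSet`, or a named character vector of sequences.
#' @param defs motif definitions (default: bundled).
#' @return an object of class `tier_table`: data.frame with one row per
#'   record (`sequence_id`, `tier`, `failed_at`), with the per-sequence
#'   witness placements in `attr(, "classifications")`.
#' @seealso [tier_histogram()], [classification_table()]
#' @export
batch_classify <- function(fasta, defs = load_definitions()) {
  seqs <- read_protein_fasta(fasta)
  ids <- dedup_ids(names(seqs))
  cls <- lapply(seq_along(seqs), function(i)
    tryCatch(classify_tier(seqs[[i]], defs, id = ids[i]),
             error = function(e) {
               warning("record '", ids[i], "' could not be classified: ",
                       conditionMessage(e), call. = FALSE)
               structure(list(sequence_id = ids[i],
                              tier = factor(NA, levels = TIER_LEVELS),
                              placements = NULL,
                              failed_at = conditionMessage(e)),
                         class = "tier_classification")
             }))
  out <- data.frame(
    sequence_id = ids,
    tier = factor(vapply(cls, function(x) as.character(x$tier), character(1)),
                  levels = TIER_LEVELS),
    failed_at = vapply(cls, function(x)
      if (is.na(x$failed_at)) NA_character_ else x$failed_at, character(1)),
    stringsAsFactors = FALSE)
  attr(out, "classifications") <- cls
  class(out) <- c("tier_table", "data.frame")
  out
}

#' Tier count histogram of a classification table
#'
#' @param x a `tier_table` from [batch_classify()].
#' @param drop_m0 drop the M0 level from the result.
#' @return named integer vector of counts over tiers.
#' @export
tier_histogram <- function(x, drop_m0 = FALSE) {
  h <- table(factor(x$tier, levels = TIER_LEVELS))
  h <- stats::setNames(as.integer(h), names(h))
  if (drop_m0) h <- h[setdiff(names(h), "M0")]
  h
}

#' Long-format classification table (1-based coordinates)
#'
#' One row per witness placement component, suitable for TSV export:
#' `sequence_id`, `tier`, `component`, `start_1based`, `end_1based`,
#' `matched_text`.  M0 (or flagged) records contribute one row with empty
#' placement fields.
#'
#' @param x a `tier_table` from [batch_classify()].
#' @return data.frame.
#' @export
classification_table <- function(x) {
  stopifnot(inherits(x, "tier_table"))
  cls <- attr(x, "classifications")
  rows <- lapply(cls, function(cl) {
    if (is.null(cl$placements))
      return(data.frame(sequence_id = cl$sequence_id,
                        tier = as.character(cl$tier),
                        component = NA_character_,
                        start_1based = NA_integer_, end_1based = NA_integer_,
                        matched_text = NA_character_))
    p <- cl$placements
    data.frame(sequence_id = cl$sequence_id, tier = as.character(cl$tier),
               component = p$component,
               start_1based = p$start + 1L, end_1based = p$end,
               matched_text = p$matched_text)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tier_table <- function(x, ...) {
  cat("<tier_table> ", nrow(x), " sequences\n", sep = "")
  h <- tier_histogram(x)
  cat("  tiers: ", paste(sprintf("%s:%d", names(h), h), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

# ---- FASTA plumbing ---------------------------------------------------------

# Accept a path, AAStringSet, or named character vector; return a named
# character vector of uppercase sequences.
read_protein_fasta <- function(fasta) {
  if (methods::is(fasta, "AAStringSet")) {
    out <- as.character(fasta)
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    out <- as.character(Biostrings::readAAStringSet(fasta))
  } else if (is.character(fasta)) {
    if (is.null(names(fasta)))
      names(fasta) <- sprintf("seq%03d", seq_along(fasta))
    out <- fasta
  } else {
    stop("fasta must be a file path, an AAStringSet, or a named character ",
         "vector", call. = FALSE)
  }
  # FASTA convention: id is the header token before the first whitespace
  names(out) <- vapply(strsplit(names(out), "\\s+"), function(x)
    if (length(x)) x[1] else "", character(1))
  toupper(out)
}

dedup_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  warning("duplicate sequence ids; suffix-deduplicated", call. = FALSE)
  make.unique(ids, sep = ".")
}

#' Write a classification table as TSV
#'
#' Tab-separated with a header line; `#`-prefixed provenance comments may be
#' prepended via `comments`.
#'
#' @param x a `tier_table` or plain data.frame.
#' @param path output path.
#' @param comments character vector of comment lines (without the leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, comments = character(0)) {
  if (inherits(x, "tier_table")) x <- classification_table(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
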