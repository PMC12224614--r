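#' Parse hmmsearch per-domain tabular output (domtblout)
#'
#' Reads the standard 23-column whitespace-delimited per-domain table written
#' by `hmmsearch --domtblout`, skipping `#` comment lines.  Malformed rows
#' are skipped with a warning naming the line number.
#'
#' @param file path to a domtblout file.
#' @return data.frame of domain hits: `target_id`, `query_name`,
#'   `query_accession`, `full_evalue`, `independent_evalue`, `env_from`,
#'   `env_to` (1-based inclusive).
#' @seealso [filter_domhits()]
#' @export
parse_domtbl <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  lines <- readLines(file)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L) {
      warning("malformed domtbl row at line ", i, "; skipped", call. = FALSE)
      return(NULL)
    }
    ev <- suppressWarnings(as.numeric(c(f[7], f[13], f[20], f[21])))
    if (anyNA(ev)) {
      warning("malformed domtbl row at line ", i, "; skipped", call. = FALSE)
      return(NULL)
    }
    data.frame(target_id = f[1], query_name = f[4], query_accession = f[5],
               full_evalue = ev[1], independent_evalue = ev[2],
               env_from = as.integer(ev[3]), env_to = as.integer(ev[4]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(target_id = character(0), query_name = character(0),
                      query_accession = character(0),
                      full_evalue = numeric(0),
                      independent_evalue = numeric(0),
                      env_from = integer(0), env_to = integer(0))
  rownames(out) <- NULL
  out
}

#' Filter domain hits by accession and e-value
#'
#' @param hits data.frame from [parse_domtbl()].
#' @param accession Pfam accession to keep (prefix match, so `"PF01738"`
#'   also matches versioned `"PF01738.21"`); `NULL` keeps all.
#' @param evalue maximum independent e-value (default 1e-5).
#' @return filtered data.frame.
#' @export
filter_domhits <- function(hits, accession = "PF01738", evalue = 1e-5) {
  keep <- hits$independent_evalue <= evalue
  if (!is.null(accession))
    keep <- keep & startsWith(hits$query_accession, accession)
  hits[keep, , drop = FALSE]
}

#' Parse SignalP 6 tabular predictions
#'
#' Accepts the tab-separated prediction summary written by SignalP 6
#' (`#`-prefixed comments; columns: id, prediction label, probabilities,
#' cleavage-site text such as `CS pos: 26-27. Pr: 0.97`).  A prediction of
#' `OTHER` means no signal peptide; the signal classes `SP`, `LIPO`, `TAT`,
#' `TATLIPO` and `PILIN` mean a signal peptide is present.  Unknown labels
#' are treated as no signal with a warning.
#'
#' @param file path to a SignalP prediction table.
#' @return data.frame: `sequence_id`, `has_signal`, `cleavage_site`
#'   (1-based first residue of the mature protein; NA without a signal),
#'   `probability`.
#' @export
parse_signalp <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  signal_labels <- c("SP", "LIPO", "TAT", "TATLIPO", "PILIN")
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 2L) f <- strsplit(trimws(ln), "\\s{2,}|\t")[[1]]
    id <- strsplit(trimws(f[1]), "\\s+")[[1]][1]
    label <- toupper(trimws(f[2]))
    has <- label %in% signal_labels
    if (!has && label != "OTHER")
      warning("unknown SignalP label '", label, "' for ", id,
              "; treated as no signal", call. = FALSE)
    cs <- NA_integer_; pr <- NA_real_
    # probability: largest numeric field among columns 3..n that is <= 1
    nums <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (any(!is.na(nums) & nums <= 1))
      pr <- max(nums[!is.na(nums) & nums <= 1])
    if (has) {
      m <- regmatches(ln, regexec("CS pos: *([0-9]+)-([0-9]+)", ln))[[1]]
      if (length(m)) cs <- as.integer(m[3])
    }
    data.frame(sequence_id = id, has_signal = has, cleavage_site = cs,
               probability = pr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence_id = character(0), has_signal = logical(0),
                      cleavage_site = integer(0), probability = numeric(0))
  rownames(out) <- NULL
  out
}

#' Screen a candidate FASTA end to end
#'
#' Orchestrates the full per-sequence screen: motif tier classification,
#' efficiency scoring, and (optionally) a PF01738 domain pre-filter column
#' from hmmsearch output and signal-peptide annotation from SignalP output.
#' One row is produced per FASTA record regardless of annotation coverage;
#' annotation ids not present in the FASTA raise a warning and are ignored.
#'
#' @param fasta FASTA path, `AAStringSet`, or named character vector.
#' @param defs motif definitions (default bundled).
#' @param scheme scoring scheme (default bundled).
#' @param reference reference sequence for alignment-based scoring.
#' @param domtbl optional path to hmmsearch domtblout for the domain
#'   pre-filter.
#' @param signalp optional path to SignalP predictions.
#' @param accession,evalue domain-filter parameters (see
#'   [filter_domhits()]).
#' @return an object of class `screen_report`: data.frame with
#'   `sequence_id`, `tier`, `raw_score`, `bin`, `dlh_domain` (logical; NA
#'   when no domtbl given), `has_signal`, `cleavage_site`,
#'   `sp_probability`; tier histogram in `attr(,"histogram")`.
#' @export
screen_fasta <- function(fasta, defs = load_definitions(),
                         scheme = load_scheme(),
                         reference = petase_reference(),
                         domtbl = NULL, signalp = NULL,
                         accession = "PF01738", evalue = 1e-5) {
  seqs <- read_protein_fasta(fasta)
  if (!length(seqs)) {
    warning("no sequences in input; empty report", call. = FALSE)
    out <- data.frame(sequence_id = character(0), tier = character(0),
                      raw_score = numeric(0), bin = character(0),
                      dlh_domain = logical(0), has_signal = logical(0),
                      cleavage_site = integer(0), sp_probability = numeric(0))
    attr(out, "histogram") <- tier_histogram(
      structure(list(tier = factor(character(0), levels = TIER_LEVELS)),
                class = c("tier_table", "data.frame")))
    class(out) <- c("screen_report", "data.frame")
    return(out)
  }
  tiers <- batch_classify(seqs, defs)
  scores <- score_fasta(seqs, scheme, reference)
  out <- data.frame(sequence_id = tiers$sequence_id,
                    tier = as.character(tiers$tier),
                    raw_score = scores$raw, bin = scores$bin,
                    dlh_domain = NA, has_signal = NA,
                    cleavage_site = NA_integer_,
                    sp_probability = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(domtbl)) {
    hits <- filter_domhits(parse_domtbl(domtbl), accession, evalue)
    unknown <- setdiff(unique(hits$target_id), out$sequence_id)
    if (length(unknown))
      warning("domtbl ids absent from FASTA: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    out$dlh_domain <- out$sequence_id %in% hits$target_id
  }
  if (!is.null(signalp)) {
    sp <- parse_signalp(signalp)
    unknown <- setdiff(sp$sequence_id, out$sequence_id)
    if (length(unknown))
      warning("SignalP ids absent from FASTA: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    m <- match(out$sequence_id, sp$sequence_id)
    out$has_signal <- sp$has_signal[m]
    out$cleavage_site <- sp$cleavage_site[m]
    out$sp_probability <- sp$probability[m]
  }
  attr(out, "histogram") <- tier_histogram(tiers)
  attr(out, "classifications") <- attr(tiers, "classifications")
  class(out) <- c("screen_report", "data.frame")
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", nrow(x), " sequences\n", sep = "")
  h <- attr(x, "histogram")
  if (!is.null(h))
    cat("  tiers: ", paste(sprintf("%s:%d", names(h), h), collapse = "  "),
        "\n", sep = "")
  invisible(x)
}
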