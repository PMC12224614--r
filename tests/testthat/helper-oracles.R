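# Independent oracles used across the suite.  These deliberately avoid the
# package's scanning/search code paths: the scanner is checked position by
# position, the tier classifier by exhaustive enumeration of placement
# combinations, and the Mann-Whitney U by literal pair counting.

# Naive position-by-position scan of one compiled component: expands every
# repeat-count combination of the pattern elements and tests each start.
naive_component_scan <- function(residues, comp_name, defs) {
  chars <- strsplit(toupper(residues), "")[[1]]
  elems <- defs$components[[comp_name]]$pattern$elements
  reps <- expand.grid(lapply(elems, function(e) e$min:e$max))
  hits <- NULL
  for (r in seq_len(nrow(reps))) {
    lens <- as.integer(reps[r, ])
    total <- sum(lens)
    if (total > length(chars)) next
    for (s in seq_len(length(chars) - total + 1L)) {
      pos <- s
      ok <- TRUE
      for (j in seq_along(elems)) {
        if (lens[j] == 0L) next
        seg <- chars[pos:(pos + lens[j] - 1L)]
        if (!is.null(elems[[j]]$set) && !all(seg %in% elems[[j]]$set)) {
          ok <- FALSE; break
        }
        pos <- pos + lens[j]
      }
      if (ok)
        hits <- rbind(hits, data.frame(component = comp_name,
                                       start = s - 1L, end = s - 1L + total))
    }
  }
  if (is.null(hits))
    return(data.frame(component = character(0), start = integer(0),
                      end = integer(0)))
  unique(hits)
}

naive_scan_all <- function(residues, defs) {
  out <- do.call(rbind, lapply(names(defs$components), function(nm)
    naive_component_scan(residues, nm, defs)))
  out[order(out$component, out$start, out$end), , drop = FALSE]
}

# Exhaustive tier satisfaction: enumerate every combination of component
# placements and test all constraints plus the shared-serine rule.
brute_tier_satisfied <- function(residues, tier, defs, scan = NULL) {
  if (is.null(scan)) scan <- naive_scan_all(residues, defs)
  plc <- lapply(tier$components, function(nm)
    which(scan$component == nm))
  if (any(vapply(plc, length, integer(1)) == 0L)) return(FALSE)
  combos <- expand.grid(plc)
  for (r in seq_len(nrow(combos))) {
    starts <- scan$start[as.integer(combos[r, ])]
    names(starts) <- tier$components
    ok <- TRUE
    for (dc in tier$constraints) {
      sep <- starts[[dc$to]] - starts[[dc$from]]
      if (sep < dc$min_sep || sep > dc$max_sep) { ok <- FALSE; break }
    }
    if (ok && all(c("ser_met", "nucleophile_elbow") %in% tier$components)) {
      if (starts[["ser_met"]] != starts[["nucleophile_elbow"]] + 2L)
        ok <- FALSE
    }
    if (ok) return(TRUE)
  }
  FALSE
}

brute_classify <- function(residues, defs) {
  scan <- naive_scan_all(residues, defs)
  sat <- vapply(defs$tiers, function(td)
    brute_tier_satisfied(residues, td, defs, scan), logical(1))
  list(tier = if (any(sat)) names(defs$tiers)[max(which(sat))] else "M0",
       satisfied = sat)
}

# Mann-Whitney U by literal pair counting, exact p by enumerating all
# group assignments (tie-free data, small n only).
brute_mw_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

brute_mw_exact_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  u_obs <- brute_mw_U(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    brute_mw_U(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Gotoh global affine alignment score (match via BLOSUM62), independent of
# Biostrings' implementation; used on short fragments only.
brute_nw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  # Biostrings convention: a gap of length L costs gap_open + L * gap_extend
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                   X[i - 1, j] - gap_extend,
                   Y[i - 1, j] - gap_open - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                   Y[i, j - 1] - gap_extend,
                   X[i, j - 1] - gap_open - gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Small helpers for fixtures built in code ------------------------------------

write_toy_fasta <- function(seqs, path) {
  con <- file(path, "wt")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[[i]], con)
  }
  close(con)
  path
}

# hmmsearch domtblout writer (22 fixed columns + description).
write_toy_domtbl <- function(hits, path) {
  lines <- c("# comment line one", "#  target name ... (toy header)")
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lines <- c(lines, paste(
      h$target_id, "-", 300, h$query_name, h$query_accession, 200,
      format(h$full_evalue), 100.0, 0.1, 1, 1, format(h$full_evalue),
      format(h$independent_evalue), 99.0, 0.1, 1, 200, h$env_from, h$env_to,
      h$env_from, h$env_to, 0.98, "toy description text"))
  }
  writeLines(lines, path)
  path
}

write_toy_signalp <- function(rows, path) {
  lines <- c("# SignalP-6.0 (toy)", "# ID\tPrediction\tOTHER\tSP\tCS Position")
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    cs <- if (!is.na(r$cs)) sprintf("CS pos: %d-%d. Pr: %.4f", r$cs - 1L,
                                    r$cs, r$pr) else ""
    lines <- c(lines, paste(r$id, r$label, sprintf("%.4f", 1 - r$pr),
                            sprintf("%.4f", r$pr), cs, sep = "\t"))
  }
  writeLines(lines, path)
  path
}
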