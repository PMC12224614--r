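# Amino-acid alphabet accepted for classification: the 20 standard residues
# plus the ambiguity code X.  X is matched by the 'x' wildcard but never by a
# named residue set, so an ambiguous residue can never satisfy a specific
# requirement (conservative: prevents false high-tier calls).
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Compile a PROSITE-style pattern
#'
#' Patterns are written in PROSITE dialect: elements separated by `-`, each
#' element one of a literal residue (`G`), a residue set (`[PG]`), an excluded
#' set (`{P}`, any standard residue except those listed), or the wildcard `x`
#' (any residue, including the ambiguity code X).  Any element may carry a
#' repeat quantifier `(n)` or `(min,max)`, e.g. `x(2,3)`.
#'
#' @param pattern character scalar, e.g. `"[PG]-G-[YF]"` or
#'   `"D-x-D-x-R-x(2,3)-F-x-C"`.
#' @param component optional component name used in error messages.
#' @return an object of class `prosite_pattern`: a list of elements, each with
#'   `set` (character vector of allowed residues, or `NULL` for the wildcard),
#'   `min` and `max` repeat counts.
#' @examples
#' compile_pattern("G-x-S-x-G")
#' @export
compile_pattern <- function(pattern, component = NULL) {
  ctx <- if (is.null(component)) "" else sprintf(" in component '%s'", component)
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty character scalar", ctx, call. = FALSE)
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(toks) || any(!nzchar(toks)))
    stop("malformed pattern '", pattern, "'", ctx, ": empty element", call. = FALSE)
  elems <- lapply(toks, function(tok) {
    min <- 1L; max <- 1L
    m <- regmatches(tok, regexec("^(.*?)\\(([0-9]+)(,([0-9]+))?\\)$", tok))[[1]]
    if (length(m)) {
      tok <- m[2]
      min <- as.integer(m[3])
      max <- if (nzchar(m[5])) as.integer(m[5]) else min
      if (max < min)
        stop("malformed quantifier in pattern '", pattern, "'", ctx, call. = FALSE)
    }
    if (tok == "x") {
      set <- NULL
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      set <- strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
    } else if (grepl("^\\{[A-Z]+\\}$", tok)) {
      excl <- strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
      set <- setdiff(AA_STANDARD, excl)
    } else if (grepl("^[A-Z]$", tok)) {
      set <- tok
    } else {
      stop("malformed pattern element '", tok, "' in '", pattern, "'", ctx,
           call. = FALSE)
    }
    if (!is.null(set)) {
      bad <- setdiff(set, AA_STANDARD)
      if (length(bad))
        stop("residue(s) ", paste(bad, collapse = ","),
             " outside the standard alphabet in pattern '", pattern, "'", ctx,
             call. = FALSE)
      if (!length(set))
        stop("empty residue set in pattern '", pattern, "'", ctx, call. = FALSE)
    }
    list(set = set, min = min, max = max)
  })
  structure(list(elements = elems, source = pattern),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern>", x$source, "\n")
  invisible(x)
}

# Minimal/maximal number of residues a compiled pattern can span.
pattern_span <- function(p) {
  mins <- vapply(p$elements, `[[`, integer(1), "min")
  maxs <- vapply(p$elements, `[[`, integer(1), "max")
  c(min = sum(mins), max = sum(maxs))
}

# All matches of a compiled pattern in a character vector of residues.
# Returns a data.frame with 0-based half-open coordinates (start, end),
# enumerating every placement at every start, including overlapping ones and
# multiple lengths arising from bounded quantifiers.
pattern_matches <- function(chars, p) {
  n <- length(chars)
  span <- pattern_span(p)
  starts <- integer(0); ends <- integer(0)
  if (n >= span[["min"]]) {
    elems <- p$elements
    k <- length(elems)
    # ends_from(i, j): exclusive 1-based end positions reachable matching
    # elements j..k starting at 1-based position i
    ends_from <- function(i, j) {
      if (j > k) return(i)
      e <- elems[[j]]
      out <- integer(0)
      for (rep in e$min:e$max) {
        if (i + rep - 1L > n) break
        ok <- if (rep == 0L) TRUE
              else if (is.null(e$set)) TRUE
              else all(chars[i:(i + rep - 1L)] %in% e$set)
        if (ok) out <- c(out, ends_from(i + rep, j + 1L))
      }
      out
    }
    for (s in seq_len(n - span[["min"]] + 1L)) {
      es <- unique(ends_from(s, 1L))
      if (length(es)) {
        starts <- c(starts, rep.int(s, length(es)))
        ends <- c(ends, es)
      }
    }
  }
  data.frame(start = starts - 1L, end = ends - 1L)  # 0-based half-open
}
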