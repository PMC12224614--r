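#' Load M1-M5 motif tier definitions
#'
#' Reads a motif definition document (JSON) and compiles it into scanner-ready
#' tier definitions.  With `config = NULL` the bundled defaults are returned:
#' nine components (nucleophile elbow, glycine quad, two aromatic clamps,
#' catalytic Asp and His, Ser-Met oxyanion hole, DxDxR(Y)xxFxC block and
#' disulfide cysteine) arranged into five cumulative tiers of increasing
#' stringency, with distance bounds measured on the *Is*PETase reference and
#' widened by ±10 residues.
#'
#' Tiers must be cumulative: every tier's component set and constraint set
#' must contain those of the tier below.  Distances are measured between
#' match start positions (anchors), N-to-C.
#'
#' @param config path to a JSON definition document, or `NULL` for the
#'   bundled defaults.
#' @return an object of class `motif_definitions`: list with `components`
#'   (named list; each has the compiled `pattern`, `role`, and optional
#'   `serine_offset`) and `tiers` (list of five tier definitions, each with
#'   `tier`, `components`, `constraints`).
#' @examples
#' defs <- load_definitions()
#' names(defs$components)
#' @export
load_definitions <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "motif_definitions.json",
                          package = "petasescan", mustWork = TRUE)
  if (!file.exists(config))
    stop("definition file not found: ", config, call. = FALSE)
  doc <- jsonlite::read_json(config, simplifyVector = FALSE)
  compile_definitions(doc)
}

# Compile and validate a parsed definition document (list form).
compile_definitions <- function(doc) {
  if (is.null(doc$components) || is.null(doc$tiers))
    stop("definition document must have 'components' and 'tiers'",
         call. = FALSE)
  comps <- list()
  for (cm in doc$components) {
    if (is.null(cm$name) || is.null(cm$pattern))
      stop("every component needs 'name' and 'pattern'", call. = FALSE)
    comps[[cm$name]] <- list(
      name = cm$name,
      pattern = compile_pattern(cm$pattern, component = cm$name),
      role = if (is.null(cm$role)) "" else cm$role,
      serine_offset = if (is.null(cm$serine_offset)) NA_integer_
                      else as.integer(cm$serine_offset)
    )
  }
  tiers <- lapply(doc$tiers, function(td) {
    if (is.null(td$tier) || is.null(td$components))
      stop("every tier needs 'tier' and 'components'", call. = FALSE)
    cn <- as.character(unlist(td$components))
    missing <- setdiff(cn, names(comps))
    if (length(missing))
      stop("tier ", td$tier, " references unknown component(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    cons <- lapply(td$constraints, function(dc) {
      if (!all(c("from", "to", "min_sep", "max_sep") %in% names(dc)))
        stop("constraint in tier ", td$tier,
             " needs from/to/min_sep/max_sep", call. = FALSE)
      if (!dc$from %in% cn || !dc$to %in% cn)
        stop("constraint in tier ", td$tier,
             " references component outside the tier", call. = FALSE)
      mn <- as.integer(dc$min_sep); mx <- as.integer(dc$max_sep)
      if (mn < 0L || mx < mn)
        stop("constraint ", dc$from, "->", dc$to, " in tier ", td$tier,
             ": need 0 <= min_sep <= max_sep", call. = FALSE)
      list(from = dc$from, to = dc$to, min_sep = mn, max_sep = mx)
    })
    list(tier = td$tier, components = cn, constraints = cons)
  })
  names(tiers) <- vapply(tiers, `[[`, character(1), "tier")
  if (!identical(names(tiers), c("M1", "M2", "M3", "M4", "M5")))
    stop("definitions must provide exactly tiers M1..M5 in order",
         call. = FALSE)
  # cumulativity: components and constraints are supersets of the tier below
  con_key <- function(cons) vapply(cons, function(dc)
    paste(dc$from, dc$to, dc$min_sep, dc$max_sep, sep = "|"), character(1))
  for (k in 2:5) {
    lo <- tiers[[k - 1]]; hi <- tiers[[k]]
    if (!all(lo$components %in% hi$components))
      stop("non-cumulative tiers: ", hi$tier, " lacks component(s) of ",
           lo$tier, ": ",
           paste(setdiff(lo$components, hi$components), collapse = ", "),
           call. = FALSE)
    if (!all(con_key(lo$constraints) %in% con_key(hi$constraints)))
      stop("non-cumulative tiers: ", hi$tier, " lacks constraint(s) of ",
           lo$tier, call. = FALSE)
  }
  structure(list(components = comps, tiers = tiers),
            class = "motif_definitions")
}

#' Serialize motif definitions back to a JSON document
#'
#' Inverse of [load_definitions()]: writing the returned object and loading it
#' again yields identical compiled definitions.
#'
#' @param defs a `motif_definitions` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_definitions <- function(defs, path) {
  stopifnot(inherits(defs, "motif_definitions"))
  doc <- list(
    components = lapply(unname(defs$components), function(cm) {
      out <- list(name = cm$name, pattern = cm$pattern$source, role = cm$role)
      if (!is.na(cm$serine_offset)) out$serine_offset <- cm$serine_offset
      out
    }),
    tiers = lapply(unname(defs$tiers), function(td) {
      list(tier = td$tier, components = as.list(td$components),
           constraints = lapply(td$constraints, function(dc)
             list(from = dc$from, to = dc$to,
                  min_sep = dc$min_sep, max_sep = dc$max_sep)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.motif_definitions <- function(x, ...) {
  cat("<motif_definitions> ", length(x$components), " components, ",
      length(x$tiers), " tiers\n", sep = "")
  for (td in x$tiers)
    cat(sprintf("  %s: %d components, %d distance constraints\n",
                td$tier, length(td$components), length(td$constraints)))
  invisible(x)
}

#' The bundled *Is*PETase reference sequence
#'
#' The 290-residue PET hydrolase of *Ideonella sakaiensis* used as the
#' calibration and numbering reference throughout the package (catalytic
#' triad S160/D206/H237, oxyanion-hole M161, active-site disulfide
#' C203-C239).
#'
#' @return a named character scalar (name = FASTA id, value = residues).
#' @examples
#' substr(petase_reference(), 158, 165)  # GWSMGGGG
#' @export
petase_reference <- function() {
  fa <- Biostrings::readAAStringSet(system.file(
    "extdata", "ispetase_reference.faa", package = "petasescan",
    mustWork = TRUE))
  out <- as.character(fa[[1]])
  names(out) <- strsplit(names(fa)[1], "\\s+")[[1]][1]
  out
}
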