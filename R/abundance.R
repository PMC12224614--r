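#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = fragments / ((gene_length/1000) * (total_mapped_fragments/1e6))`.
#' Vectorized; invariant under uniform scaling of fragment counts and
#' totals.
#'
#' @param fragments non-negative fragment counts.
#' @param gene_length gene lengths in bp (> 0).
#' @param total_mapped_fragments per-sample totals (> 0).
#' @return numeric FPKM values.
#' @examples
#' compute_fpkm(10, 1000, 1e6)  # 10
#' @export
compute_fpkm <- function(fragments, gene_length, total_mapped_fragments) {
  if (any(fragments < 0, na.rm = TRUE))
    stop("fragments must be >= 0", call. = FALSE)
  if (any(gene_length <= 0, na.rm = TRUE))
    stop("gene_length must be > 0", call. = FALSE)
  if (any(total_mapped_fragments <= 0, na.rm = TRUE))
    stop("total_mapped_fragments must be > 0", call. = FALSE)
  fragments / ((gene_length / 1000) * (total_mapped_fragments / 1e6))
}

#' Add an FPKM column to a per-sample fragment-count table
#'
#' @param counts data.frame with columns `sample_id`, `gene_id`,
#'   `fragments`, `gene_length`, `total_mapped_fragments`.
#' @return `counts` with an `fpkm` column.
#' @export
fpkm_table <- function(counts) {
  need <- c("sample_id", "gene_id", "fragments", "gene_length",
            "total_mapped_fragments")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  counts$fpkm <- compute_fpkm(counts$fragments, counts$gene_length,
                              counts$total_mapped_fragments)
  counts
}

#' Marker-normalized per-sample variant abundance
#'
#' Per sample, sums the FPKM of all variant genes and divides by the summed
#' FPKM of the single-copy marker (recA) genes:
#' `value = sum(FPKM[variants]) / sum(FPKM[markers])`.  Multiple marker
#' copies per sample are summed.  Samples without marker signal (no marker
#' rows, or marker FPKM 0) yield a missing value with a warning.
#'
#' @param counts counts table (see [fpkm_table()]); an existing `fpkm`
#'   column is used, otherwise computed.
#' @param variant_ids gene ids of the variants to aggregate (e.g. the
#'   M5-PETase catalog entries).
#' @param marker_ids gene ids of the recA marker genes.
#' @return data.frame: `sample_id`, `value` (dimensionless ratio; NA when
#'   marker absent), `detected` (`value > 0`).
#' @export
normalize_by_marker <- function(counts, variant_ids, marker_ids) {
  if (!"fpkm" %in% names(counts)) counts <- fpkm_table(counts)
  samples <- unique(counts$sample_id)
  vsum <- tapply(counts$fpkm[counts$gene_id %in% variant_ids],
                 counts$sample_id[counts$gene_id %in% variant_ids], sum)
  msum <- tapply(counts$fpkm[counts$gene_id %in% marker_ids],
                 counts$sample_id[counts$gene_id %in% marker_ids], sum)
  v <- ifelse(is.na(vsum[samples]), 0, vsum[samples])
  m <- as.numeric(msum[samples])
  value <- ifelse(is.na(m) | m == 0, NA_real_, v / m)
  bad <- samples[is.na(value)]
  if (length(bad))
    warning("no marker FPKM for sample(s): ", paste(bad, collapse = ", "),
            "; value set to NA", call. = FALSE)
  data.frame(sample_id = samples, value = as.numeric(value),
             detected = !is.na(value) & value > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default ocean depth layers
#'
#' Half-open bins in meters: \[0,100), \[100,500), \[500,1000),
#' \[1000,2000), \[2000,3000), \[3000,Inf).
#' @return numeric vector of bin edges.
#' @export
depth_layers <- function() c(0, 100, 500, 1000, 2000, 3000, Inf)

depth_layer_labels <- function(edges = depth_layers()) {
  lo <- edges[-length(edges)]; hi <- edges[-1]
  ifelse(is.infinite(hi), sprintf(">%g m", lo),
         sprintf("%g-%g m", lo, hi))
}

#' Detection fraction and mean abundance by depth layer
#'
#' Assigns each sample to its (half-open) depth bin and reports, per bin,
#' the fraction of samples in which the variant set was detected and the
#' mean ± SE of the normalized abundance over detected samples only
#' (`SE = sd/sqrt(n)`).  Empty bins report fraction 0 and missing mean.
#'
#' @param normalized data.frame with `sample_id`, `value`, `detected` (from
#'   [normalize_by_marker()]) plus a `depth` column in meters.
#' @param edges depth bin edges (default [depth_layers()]).
#' @return data.frame: `layer`, `depth_min`, `n`, `n_detected`, `fraction`,
#'   `mean`, `se`.
#' @export
depth_layer_summary <- function(normalized, edges = depth_layers()) {
  stopifnot(all(c("value", "depth") %in% names(normalized)))
  if (any(normalized$depth < 0, na.rm = TRUE))
    stop("depths must be >= 0", call. = FALSE)
  if (!"detected" %in% names(normalized))
    normalized$detected <- !is.na(normalized$value) & normalized$value > 0
  bin <- cut(normalized$depth, breaks = edges, right = FALSE,
             include.lowest = FALSE, labels = depth_layer_labels(edges))
  out <- do.call(rbind, lapply(levels(bin), function(lb) {
    sel <- which(bin == lb)
    det <- sel[normalized$detected[sel]]
    vals <- normalized$value[det]
    data.frame(layer = lb,
               depth_min = edges[match(lb, levels(bin))],
               n = length(sel), n_detected = length(det),
               fraction = if (length(sel)) length(det) / length(sel) else 0,
               mean = if (length(det)) mean(vals) else NA_real_,
               se = if (length(det) > 1) sd(vals) / sqrt(length(det))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Depth trend of normalized abundance with station grouping
#'
#' Fits a linear mixed model of (by default log10-transformed) normalized
#' abundance on depth in kilometers with a per-station random intercept,
#' over detected samples only.  With a single station the model degenerates
#' and an ordinary regression is fitted with a warning.  The depth-slope
#' p-value is a Wald normal approximation on the t statistic.
#'
#' @param normalized data.frame with `value`, `depth` (m) and `station`
#'   columns.
#' @param transform `"log10"` (default) or `"identity"` response transform.
#' @return list: `slope`, `se`, `p`, `n`, `n_stations`, `transform`,
#'   `model`.
#' @export
depth_trend <- function(normalized, transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  stopifnot(all(c("value", "depth", "station") %in% names(normalized)))
  d <- normalized[!is.na(normalized$value) & normalized$value > 0, ,
                  drop = FALSE]
  if (length(unique(d$depth)) < 2L)
    stop("degenerate design: need >= 2 distinct depths", call. = FALSE)
  d$y <- if (transform == "log10") log10(d$value) else d$value
  d$depth_km <- d$depth / 1000
  ns <- length(unique(d$station))
  if (ns < 2L) {
    warning("single station: falling back to ordinary regression",
            call. = FALSE)
    fit <- stats::lm(y ~ depth_km, data = d)
    sm <- summary(fit)$coefficients
    slope <- sm["depth_km", "Estimate"]; se <- sm["depth_km", "Std. Error"]
    p <- sm["depth_km", "Pr(>|t|)"]
  } else {
    fit <- lme4::lmer(y ~ depth_km + (1 | station), data = d,
                      REML = TRUE)
    sm <- summary(fit)$coefficients
    slope <- sm["depth_km", "Estimate"]; se <- sm["depth_km", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(slope / se))
  }
  list(slope = unname(slope), se = unname(se), p = unname(p),
       n = nrow(d), n_stations = ns, transform = transform, model = fit)
}

#' PETase / MHETase co-occurrence counts
#'
#' Cross-tabulates per-sample presence of the PETase variant set and the
#' MHETase gene set (KEGG KO K21105 annotations).
#'
#' @param presence data.frame with logical columns `has_petase`,
#'   `has_mhetase` (one row per sample).
#' @return named integer vector: `both`, `petase_only`, `mhetase_only`,
#'   `neither` (sums to the number of samples).
#' @export
cooccurrence <- function(presence) {
  stopifnot(all(c("has_petase", "has_mhetase") %in% names(presence)))
  p <- as.logical(presence$has_petase)
  m <- as.logical(presence$has_mhetase)
  c(both = sum(p & m), petase_only = sum(p & !m),
    mhetase_only = sum(!p & m), neither = sum(!p & !m))
}
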