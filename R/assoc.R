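EARTH_RADIUS_KM <- 6371
KM_PER_DEGREE <- pi / 180 * EARTH_RADIUS_KM  # ~111.195 km per degree of arc

#' Great-circle (haversine) distance in kilometers
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon, what) {
  if (any(lat < -90 | lat > 90, na.rm = TRUE))
    stop(what, ": latitude out of [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180, na.rm = TRUE))
    stop(what, ": longitude out of [-180, 180]", call. = FALSE)
}

#' Match plastic-survey records to sequencing samples
#'
#' For each plastic record, finds the nearest eligible sample location
#' within the search radius and emits one association per sample collected
#' at that location ("same location" = coordinates identical after rounding
#' to 4 decimal places).  Eligible samples are those not deeper than
#' `max_depth` (surface samples, since plastic surveys are surface tows).
#' Plastic records with no in-radius sample are discarded; one sample may
#' serve many plastic records.
#'
#' @param plastic data.frame: `record_id`, `lat`, `lon`, `concentration`
#'   (g/km^2, >= 0).
#' @param samples data.frame: `sample_id`, `lat`, `lon`, `depth` (m).
#' @param radius_deg search radius in degrees of arc (default 5, i.e.
#'   ~556 km great-circle).
#' @param max_depth maximum sample depth in meters (default 10).
#' @param metric `"haversine"` (great-circle, default) or `"degree"`
#'   (flat Euclidean distance in degrees, for sensitivity checks).
#' @return data.frame of associations: `record_id`, `sample_id`,
#'   `distance_km` (NA under the degree metric), `distance_deg`,
#'   `concentration`, `depth`.
#' @export
match_records <- function(plastic, samples, radius_deg = 5, max_depth = 10,
                          metric = c("haversine", "degree")) {
  metric <- match.arg(metric)
  stopifnot(radius_deg > 0)
  check_coords(plastic$lat, plastic$lon, "plastic")
  check_coords(samples$lat, samples$lon, "samples")
  if (any(plastic$concentration < 0, na.rm = TRUE))
    stop("plastic concentration must be >= 0", call. = FALSE)
  eligible <- samples[samples$depth <= max_depth, , drop = FALSE]
  empty <- data.frame(record_id = character(0), sample_id = character(0),
                      distance_km = numeric(0), distance_deg = numeric(0),
                      concentration = numeric(0), depth = numeric(0))
  if (!nrow(eligible) || !nrow(plastic)) return(empty)
  # sample locations: identical rounded coordinates collapse to one location
  lockey <- paste(round(eligible$lat, 4), round(eligible$lon, 4), sep = "/")
  locs <- !duplicated(lockey)
  loc_lat <- eligible$lat[locs]; loc_lon <- eligible$lon[locs]
  loc_key <- lockey[locs]
  radius_km <- radius_deg * KM_PER_DEGREE
  rows <- lapply(seq_len(nrow(plastic)), function(i) {
    if (metric == "haversine") {
      d_km <- haversine_km(plastic$lat[i], plastic$lon[i], loc_lat, loc_lon)
      d <- d_km; lim <- radius_km
    } else {
      d <- sqrt((plastic$lat[i] - loc_lat)^2 + (plastic$lon[i] - loc_lon)^2)
      d_km <- rep(NA_real_, length(d)); lim <- radius_deg
    }
    j <- which.min(d)
    if (!length(j) || d[j] > lim) return(NULL)
    members <- which(lockey == loc_key[j])
    data.frame(record_id = plastic$record_id[i],
               sample_id = eligible$sample_id[members],
               distance_km = if (metric == "haversine") d_km[j]
                             else d[j] * KM_PER_DEGREE,
               distance_deg = if (metric == "haversine") d[j] / KM_PER_DEGREE
                              else d[j],
               concentration = plastic$concentration[i],
               depth = eligible$depth[members],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  The U statistic is computed from ranks with
#' midranks for ties; the p-value uses the exact null distribution when
#' `n1*n2 <= 400` and the data are tie-free, and the normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list: `U` (for `x`), `U2` (for `y`; `U + U2 = n1*n2`),
#'   `p_two_sided`, `method`, per-group `mean`, `se`, `n`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    method <- "exact"
    p <- if (U > n1 * n2 / 2)
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, n1, n2)
    p <- min(1, p)
  } else {
    method <- "normal approximation with tie correction"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, U2 = n1 * n2 - U, p_two_sided = p, method = method,
       mean_x = mean(x), se_x = stats::sd(x) / sqrt(n1), n_x = n1,
       mean_y = mean(y), se_y = stats::sd(y) / sqrt(n2), n_y = n2)
}

#' Plastic presence/absence contrast of normalized abundance
#'
#' Splits association records into plastic-present (`concentration > 0`)
#' and plastic-absent (`concentration == 0`) groups and compares their
#' normalized abundances with the two-sided Mann-Whitney test.
#'
#' @param associations data.frame with `concentration` and `abundance`
#'   columns (e.g. [match_records()] output joined with normalized
#'   abundance).
#' @return list: `mann_whitney` ([mann_whitney()] result with presence as
#'   `x`), `mean_presence`, `se_presence`, `n_presence`, `mean_absence`,
#'   `se_absence`, `n_absence`.
#' @export
presence_absence_test <- function(associations) {
  stopifnot(all(c("concentration", "abundance") %in% names(associations)))
  pres <- associations$abundance[associations$concentration > 0]
  abs_ <- associations$abundance[associations$concentration == 0]
  if (!length(pres) || !length(abs_))
    stop("both presence and absence groups must be non-empty",
         call. = FALSE)
  mw <- mann_whitney(pres, abs_)
  list(mann_whitney = mw,
       mean_presence = mw$mean_x, se_presence = mw$se_x, n_presence = mw$n_x,
       mean_absence = mw$mean_y, se_absence = mw$se_y, n_absence = mw$n_y)
}

#' Ordinary least-squares fit of abundance on plastic concentration
#'
#' Linear relationship on untransformed values by default (`transform`
#' applies the same transform to both axes before fitting).
#'
#' @param concentration,abundance numeric vectors (n >= 3).
#' @param transform `"identity"` (default) or `"log10p"` (log10(1+v)).
#' @return list: `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linear_fit <- function(concentration, abundance,
                       transform = c("identity", "log10p")) {
  transform <- match.arg(transform)
  keep <- !is.na(concentration) & !is.na(abundance)
  x <- concentration[keep]; y <- abundance[keep]
  if (length(x) < 3L) stop("need at least 3 complete observations",
                           call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in concentration",
                              call. = FALSE)
  if (transform == "log10p") { x <- log10(1 + x); y <- log10(1 + y) }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients["x", "Pr(>|t|)"]),
       n = length(x), model = fit)
}

#' Full plastic-association analysis
#'
#' Matches plastic records to surface samples, joins normalized abundance,
#' and computes the presence/absence contrast and the linear relationship.
#'
#' @param plastic,samples see [match_records()].
#' @param abundance data.frame `sample_id`, `value` (marker-normalized).
#' @param ... passed to [match_records()].
#' @return list: `associations` (with an `abundance` column),
#'   `presence_absence`, `linear`.
#' @export
plastic_association <- function(plastic, samples, abundance, ...) {
  assoc <- match_records(plastic, samples, ...)
  m <- match(assoc$sample_id, abundance$sample_id)
  assoc$abundance <- abundance$value[m]
  if (anyNA(assoc$abundance))
    warning("association sample(s) without abundance value dropped",
            call. = FALSE)
  assoc <- assoc[!is.na(assoc$abundance), , drop = FALSE]
  list(associations = assoc,
       presence_absence = presence_absence_test(assoc),
       linear = linear_fit(assoc$concentration, assoc$abundance))
}
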