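test_that("haversine distances match known geometry", {
  # one degree of arc along a meridian ~ 111.195 km
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-3)
  expect_equal(haversine_km(0, 0, 0, 1), 111.195, tolerance = 1e-3)
  expect_equal(haversine_km(45, 10, 45, 10), 0)
  # symmetric
  expect_equal(haversine_km(12, 40, -30, 100), haversine_km(-30, 100, 12, 40))
})

test_that("radius and depth semantics of record matching", {
  samples <- data.frame(sample_id = "s1", lat = 0, lon = 0, depth = 5)
  # nearest sample ~611 km away under a 556 km radius -> discarded
  far <- data.frame(record_id = "p1", lat = 5.5, lon = 0, concentration = 10)
  expect_equal(nrow(match_records(far, samples)), 0)
  near <- data.frame(record_id = "p2", lat = 4.5, lon = 0, concentration = 10)
  m <- match_records(near, samples)
  expect_equal(m$sample_id, "s1")
  expect_equal(m$distance_km, haversine_km(4.5, 0, 0, 0))
  # a nearer but deep sample is excluded by the depth pre-filter
  samples2 <- rbind(samples,
                    data.frame(sample_id = "deep", lat = 4.4, lon = 0,
                               depth = 200))
  m2 <- match_records(near, samples2)
  expect_equal(m2$sample_id, "s1")
  # co-located samples are all assigned to the same plastic record
  samples3 <- rbind(samples,
                    data.frame(sample_id = "s1b", lat = 0, lon = 0,
                               depth = 8))
  m3 <- match_records(near, samples3)
  expect_setequal(m3$sample_id, c("s1", "s1b"))
  expect_equal(m3$record_id, c("p2", "p2"))
})

test_that("matching agrees with an all-pairs brute-force oracle on a synthetic grid", {
  set.seed(33)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:10),
                        lat = runif(10, -40, 40),
                        lon = runif(10, -170, 170),
                        depth = sample(c(5, 5, 5, 50), 10, TRUE))
  plastic <- data.frame(record_id = sprintf("p%02d", 1:20),
                        lat = runif(20, -40, 40),
                        lon = runif(20, -170, 170),
                        concentration = rlnorm(20, 4, 1))
  got <- match_records(plastic, samples)
  # oracle: for each record, nearest eligible sample by exhaustive search
  eligible <- samples[samples$depth <= 10, ]
  radius_km <- 5 * pi / 180 * 6371
  want <- NULL
  for (i in seq_len(nrow(plastic))) {
    d <- haversine_km(plastic$lat[i], plastic$lon[i], eligible$lat,
                      eligible$lon)
    j <- which.min(d)
    if (d[j] <= radius_km)
      want <- rbind(want, data.frame(record_id = plastic$record_id[i],
                                     sample_id = eligible$sample_id[j]))
  }
  if (is.null(want)) want <- data.frame(record_id = character(0),
                                        sample_id = character(0))
  expect_equal(got[, c("record_id", "sample_id")],
               want, ignore_attr = TRUE)
  # every emitted association is in radius and at most 10 m deep
  expect_true(all(got$distance_km <= radius_km))
  expect_true(all(got$depth <= 10))
  # stability under permutation of input row order
  perm <- match_records(plastic[sample(nrow(plastic)), ],
                        samples[sample(nrow(samples)), ])
  key <- function(d) paste(d$record_id, d$sample_id)
  expect_setequal(key(perm), key(got))
})

test_that("Mann-Whitney U matches brute-force pair counting and wilcox.test", {
  # {1,2,3} vs {4,5,6}: U = 0 for the lower group, exact p by enumeration
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$U2, 9)
  expect_equal(mw$p_two_sided, brute_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mw$p_two_sided, 0.1)  # 2 * 1/20
  # identical groups: U = n1*n2/2
  expect_equal(mann_whitney(c(2, 4, 9), c(2, 4, 9))$U, 4.5)
  # exact branch against brute force and wilcox.test for n <= 30, no ties
  set.seed(71)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq(0.5, 50, by = 0.5), n1)
    y <- sample(setdiff(seq(0.5, 50, by = 0.5), x), n2)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U, brute_mw_U(x, y))
    expect_equal(mw$p_two_sided, brute_mw_exact_p(x, y))
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$p_two_sided, wt$p.value)
  }
  # U1 + U2 = n1*n2 on arbitrary inputs including ties
  for (i in 1:20) {
    x <- sample(1:8, sample(3:40, 1), TRUE)
    y <- sample(1:8, sample(3:40, 1), TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U + mw$U2, length(x) * length(y))
    expect_equal(mw$U, brute_mw_U(x, y))
  }
  # tie-corrected normal approximation agrees with wilcox.test
  set.seed(72)
  x <- sample(1:10, 60, TRUE); y <- sample(2:12, 45, TRUE)
  mw <- mann_whitney(x, y)
  wt <- stats::wilcox.test(x, y, correct = TRUE)
  expect_equal(mw$p_two_sided, wt$p.value, tolerance = 1e-10)
  expect_match(mw$method, "tie correction")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("presence/absence contrast reports group statistics", {
  assoc <- data.frame(concentration = c(0, 0, 0, 10, 20, 400),
                      abundance = c(0.001, 0.002, 0.003, 0.02, 0.03, 0.04))
  pa <- presence_absence_test(assoc)
  expect_equal(pa$n_presence, 3)
  expect_equal(pa$n_absence, 3)
  expect_equal(pa$mean_absence, 0.002)
  expect_equal(pa$mean_presence, 0.03)
  expect_equal(pa$se_absence, sd(c(0.001, 0.002, 0.003)) / sqrt(3))
  expect_error(presence_absence_test(
    data.frame(concentration = c(1, 2), abundance = c(1, 2))), "non-empty")
})

test_that("linear fit handles collinear, null and degenerate inputs", {
  # perfectly collinear -> R^2 = 1 (summary.lm warns about the perfect fit)
  lf <- suppressWarnings(linear_fit(1:10, 3 + 2 * (1:10)))
  expect_equal(lf$r_squared, 1)
  expect_equal(lf$slope, 2)
  expect_equal(lf$intercept, 3)
  expect_error(linear_fit(rep(1, 5), 1:5), "zero variance")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
  # y independent of x: slope p > 0.05 in >= 90% of 200 seeds, R^2 near 0
  rejections <- 0L; r2 <- numeric(200)
  for (seed in 1:200) {
    set.seed(seed)
    x <- rlnorm(500, 4, 1); y <- rlnorm(500, 0, 1)
    lf <- linear_fit(x, y)
    if (lf$p <= 0.05) rejections <- rejections + 1L
    r2[seed] <- lf$r_squared
  }
  expect_lte(rejections, 20L)
  expect_lt(stats::median(r2), 0.01)
})

test_that("the end-to-end association pipeline is coherent on a simulated survey", {
  sv <- gen_survey(survey_gen_spec(n_matched = 300, n_unmatched = 12,
                                   n_deep_decoys = 10, seed = 14))
  pa <- plastic_association(sv$plastic, sv$samples, sv$abundance)
  expect_equal(nrow(pa$associations), 300)   # unmatched discarded
  expect_false(any(startsWith(pa$associations$sample_id, "D")))  # deep gone
  expect_true(all(pa$associations$distance_km <= 5 * pi / 180 * 6371))
  expect_equal(pa$presence_absence$n_presence +
                 pa$presence_absence$n_absence, 300)
  expect_lt(pa$presence_absence$mann_whitney$p_two_sided, 0.001)
  expect_gt(pa$presence_absence$mean_presence,
            pa$presence_absence$mean_absence)
  expect_true(pa$linear$r_squared >= 0 && pa$linear$r_squared <= 1)
})
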