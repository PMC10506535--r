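# Lipid-droplet segmentation, density, heterogeneity and group statistics.

test_that("ratio map is elementwise with an invalid-pixel guard", {
  s <- array(0.4, c(6, 6, 2))
  b <- band_image(s, c(2847, 2933))
  r <- ratio_map(b)
  expect_equal(as.vector(unclass(r)), rep(0.4 / (0.4 + 1e-6), 36))
  expect_true(all(attr(r, "valid")))
  s2 <- s; s2[1:3, , 2] <- 0
  r2 <- ratio_map(band_image(s2, c(2847, 2933)))
  expect_false(any(attr(r2, "valid")[1:3, ]))
  expect_true(all(attr(r2, "valid")[4:6, ]))
  expect_error(ratio_map(band_image(s, c(2847, 2960))), "2933")
  expect_error(ratio_map(b, epsilon = 0), "epsilon")
})

test_that("phantom lipid pixels sit above 1 and protein tissue below on the ratio map", {
  lib <- make_spectral_library(2)
  mask <- generate_tissue_mask(7, c(96, 96), "moderate", 3,
                               ld_area_fraction = 0.05)
  cube <- render_cube(mask, lib, noise_sd = 0, seed = 2)
  r <- ratio_map(sample_bands(cube))
  ld <- unclass(mask) == MASK_CLASSES[["lipid_droplet"]]
  stroma <- unclass(mask) == MASK_CLASSES[["stroma"]]
  expect_true(all(unclass(r)[ld] > 1))
  expect_true(all(unclass(r)[stroma] < 1))
})

test_that("segmentation thresholds monotonically and filters small components", {
  set.seed(3)
  r <- structure(matrix(runif(400, 0, 2), 20, 20),
                 valid = matrix(TRUE, 20, 20))
  expect_false(any(segment_ld(r, threshold = 2.5)))
  m_lo <- segment_ld(r, 0.5)
  m_hi <- segment_ld(r, 1.2)
  expect_true(all(m_lo[m_hi]))  # higher threshold is a subset
  # min_size = 2 removes all single-pixel components
  m2 <- segment_ld(r, 1.2, min_size = 2)
  lab <- EBImage::bwlabel(m2)
  if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 2))
  one_px <- structure(rbind(c(0, 0, 0), c(0, 9, 0), c(0, 0, 0)),
                      valid = matrix(TRUE, 3, 3))
  expect_false(any(segment_ld(one_px, 1, min_size = 2)))
})

test_that("noiseless phantom droplets are recovered at the library threshold", {
  lib <- make_spectral_library(4)
  mask <- generate_tissue_mask(9, c(128, 128), "moderate", 4,
                               ld_area_fraction = 0.05)
  cube <- render_cube(mask, lib, noise_sd = 0, seed = 4)
  r <- ratio_map(sample_bands(cube))
  m <- segment_ld(r, ld_default_threshold(lib))
  truth <- unclass(mask) == MASK_CLASSES[["lipid_droplet"]]
  recall <- sum(m & truth) / sum(truth)
  precision <- sum(m & truth) / sum(m)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("densities and ROI handling behave at the extremes", {
  roi <- roi_annotation(matrix(TRUE, 5, 5), "low")
  expect_equal(ld_density(matrix(FALSE, 5, 5), roi)$density, 0)
  expect_equal(ld_density(matrix(TRUE, 5, 5), roi)$density, 1)
  expect_error(roi_annotation(matrix(FALSE, 5, 5), "low"), "empty")
  # polygon ROIs rasterise sensibly
  sq <- roi_annotation(cbind(c(1, 4, 4, 1), c(1, 1, 4, 4)), "low",
                       shape = c(6, 6))
  expect_equal(sum(sq$mask), 9)
})

test_that("density estimates are unbiased on noiseless phantoms", {
  lib <- make_spectral_library(1)
  thr <- ld_default_threshold(lib)
  errs <- vapply(1:10, function(s) {
    mask <- generate_tissue_mask(100 + s, c(96, 96), "moderate", 3,
                                 ld_area_fraction = 0.05)
    cube <- render_cube(mask, lib, noise_sd = 0, seed = s)
    r <- ratio_map(sample_bands(cube))
    m <- segment_ld(r, thr)
    roi_m <- unclass(mask) %in% MASK_CLASSES[c("epithelium", "lipid_droplet")]
    dim(roi_m) <- dim(unclass(mask))
    truth <- sum(unclass(mask) == MASK_CLASSES[["lipid_droplet"]]) / sum(roi_m)
    ld_density(m, roi_annotation(roi_m, "moderate"))$density - truth
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.002)
})

test_that("heterogeneity matches the hand-computed quartile case and is scale invariant", {
  expect_equal(heterogeneity(rep(3.7, 10)), 0)
  expect_equal(heterogeneity(c(1, 2, 3, 4, 5)), 2 / 3, tolerance = 1e-12)
  v <- runif(50, 1, 4)
  expect_equal(heterogeneity(v), heterogeneity(137.5 * v), tolerance = 1e-12)
  expect_error(heterogeneity(c(-5, 1)), "positive")
  expect_error(heterogeneity(numeric(0)), "nonempty")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares and classical identities", {
  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # {1,2} vs {5,6}: SSB = 16, SSW = 1, F = 32
  hand <- anova_oneway(list(c(1, 2), c(5, 6)))
  expect_equal(hand$ss_between, 16)
  expect_equal(hand$ss_within, 1)
  expect_equal(hand$F, 32)
  # two groups: F equals the squared pooled t statistic
  set.seed(11)
  a <- rnorm(8); b <- rnorm(9, 1)
  ft <- anova_oneway(list(a, b))
  tt <- pairwise_t(list(x = a, y = b))
  expect_equal(ft$F, tt$t^2, tolerance = 1e-12)
  # and the standard-library fit agrees (independent route)
  df <- data.frame(y = c(a, b), g = rep(c("a", "b"), c(8, 9)))
  ref <- anova(stats::aov(y ~ g, df))
  expect_equal(ft$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(ft$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_error(anova_oneway(list(c(2, 2), c(2, 2))), "undefined")
})

test_that("pairwise t tests match hand arithmetic and the standard library", {
  ident <- pairwise_t(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  hand <- pairwise_t(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(hand$t, -3 * sqrt(3 / 2), tolerance = 1e-12)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(hand$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(hand$p, ref$p.value, tolerance = 1e-12)
  # all unordered pairs are covered
  p3 <- pairwise_t(list(a = 1:3, b = 2:4, c = 3:5))
  expect_equal(nrow(p3), 3)
  # Welch variant agrees with t.test(var.equal = FALSE)
  w <- pairwise_t(list(a = c(1, 2, 3, 7), b = c(4, 5, 6)), pooled = FALSE)
  refw <- stats::t.test(c(1, 2, 3, 7), c(4, 5, 6))
  expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$p, refw$p.value, tolerance = 1e-12)
})

test_that("pairwise t p-values agree with a permutation null", {
  set.seed(21)
  a <- rnorm(6); b <- rnorm(6, 1.2)
  p_t <- pairwise_t(list(a = a, b = b))$p
  pooled <- c(a, b)
  stat <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  obs <- abs(stat(a, b))
  perms <- replicate(20000, {
    idx <- sample(12, 6)
    abs(stat(pooled[idx], pooled[-idx]))
  })
  expect_lt(abs(mean(perms >= obs - 1e-12) - p_t), 0.01)
})

test_that("the full report aggregates by class with bookkeeping and guards", {
  cohort <- make_ld_cohort(n_per_class = 4, seed = 2, shape = c(64, 64))
  thr <- ld_default_threshold(attr(cohort, "library"))
  rep_ <- ld_report(cohort, threshold = thr)
  expect_setequal(names(rep_$densities),
                  c("stroma", "low", "moderate", "high"))
  expect_equal(unname(rep_$n), rep(4L, 4))
  expect_equal(rep_$threshold, thr)
  expect_s3_class(glance(rep_), "data.frame")
  expect_equal(nrow(tidy(rep_)), 16)
  # one usable class only -> error after exclusion warning
  two <- cohort[c(1, 5)]
  expect_error(suppressWarnings(ld_report(two, thr)), "at least 2 classes")
  p <- autoplot(rep_)
  expect_s3_class(p, "ggplot")
})
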