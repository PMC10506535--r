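# Synthetic tissue phantom: spectra, masks, renders, stacks, datasets.

test_that("spectral library has the expected classes, normalisation and band ordering", {
  lib <- make_spectral_library(seed = 3)
  expect_setequal(names(lib), c("stroma", "nuclei", "epithelium",
                                "lipid_droplet"))
  for (cls in names(lib)) {
    expect_equal(max(lib[[cls]]), 1)
    expect_true(all(lib[[cls]] >= 0))
  }
  expect_gt(spectral_ratio(lib, "lipid_droplet"), 1)
  for (cls in c("stroma", "nuclei", "epithelium")) {
    expect_lt(spectral_ratio(lib, cls), 1)
  }
  # evaluating the constructed peak sums directly at the two shifts gives
  # the same ordering (independent of the library plumbing)
  axis <- wavenumber_axis()
  pk <- srstain:::.peak_tables
  raw_ratio <- function(peaks) {
    s <- srstain:::.gauss_sum(axis, peaks)
    s[which(axis == 2848)] / s[which(axis == 2932)]
  }
  expect_gt(raw_ratio(pk$lipid_droplet), 1)
  expect_lt(raw_ratio(pk$stroma), 1)
  # seeded determinism
  expect_identical(make_spectral_library(7), make_spectral_library(7))
  expect_false(identical(make_spectral_library(7), make_spectral_library(8)))
})

test_that("tissue masks partition the image and honour gland/droplet requests", {
  m0 <- generate_tissue_mask(1, c(64, 64), gland_count = 0)
  expect_setequal(unique(as.vector(m0)),
                  unname(MASK_CLASSES[c("background", "stroma")]))
  m <- generate_tissue_mask(2, c(128, 128), "low", gland_count = 4,
                            ld_area_fraction = 0.05)
  cc <- class_counts(m)
  expect_equal(sum(cc), 128 * 128)
  frac <- cc[["lipid_droplet"]] / cc[["epithelium"]]
  expect_gte(frac, 0.045)
  expect_lte(frac, 0.055)
  expect_identical(
    generate_tissue_mask(5, c(96, 96), "moderate", 3, 0.02),
    generate_tissue_mask(5, c(96, 96), "moderate", 3, 0.02)
  )
  # droplets only ever replace epithelium
  m2 <- generate_tissue_mask(2, c(128, 128), "low", 4, 0)
  changed <- unclass(m) != unclass(m2)
  expect_true(all(unclass(m2)[changed] == MASK_CLASSES[["epithelium"]]))
  expect_error(generate_tissue_mask(1, c(64, 64), gland_count = 0,
                                    ld_area_fraction = 0.1),
               "unattainable")
  expect_error(generate_tissue_mask(1, c(64, 64), ld_area_fraction = 0.5),
               "0, 0.2")
})

test_that("grade classes change gland architecture as specified", {
  low <- generate_tissue_mask(4, c(128, 128), "low", 4)
  mod <- generate_tissue_mask(4, c(128, 128), "moderate", 4)
  high <- generate_tissue_mask(4, c(128, 128), "high", 4)
  # open lumens for low, small for moderate, none for high
  expect_gt(class_counts(low)[["lumen"]], class_counts(mod)[["lumen"]])
  expect_equal(class_counts(high)[["lumen"]], 0L)
  expect_gt(class_counts(high)[["epithelium"]],
            class_counts(low)[["epithelium"]])
})

test_that("cube render is the class spectrum times brightness, plus calibrated noise", {
  lib <- make_spectral_library(1)
  lab <- matrix(MASK_CLASSES[["stroma"]], 32, 32)
  mask <- label_mask(lab)
  cube <- render_cube(mask, lib, noise_sd = 0, blur_sigma = 0, seed = 2)
  expect_equal(dim(cube)[3], length(wavenumber_axis()))
  bright <- attr(cube, "brightness")
  expected <- outer(as.vector(bright), lib$stroma)
  expect_equal(as.vector(matrix(as_bare_array(cube), 32 * 32,
                                dim(cube)[3])),
               as.vector(expected), tolerance = 1e-12)
  # empirical residual SD within 20% of the requested noise level
  noisy <- render_cube(mask, lib, noise_sd = 0.01, blur_sigma = 0, seed = 2)
  resid <- as_bare_array(noisy) - as_bare_array(cube)
  # per-band residual SD, away from the clipped-at-zero tail bands
  per_band <- apply(resid, 3, sd)
  keep <- lib$stroma > 0.05
  expect_true(all(abs(per_band[keep] - 0.01) / 0.01 < 0.2))
  expect_error(render_cube(mask, lib[c("nuclei")], noise_sd = 0),
               "missing")
})

test_that("band sampling picks nearest axis entries with lower-shift ties", {
  lib <- make_spectral_library(1)
  mask <- generate_tissue_mask(1, c(64, 64))
  cube <- render_cube(mask, lib, noise_sd = 0, seed = 1)
  bands <- sample_bands(cube)
  expect_equal(attr(bands, "shifts"), DEFAULT_BAND_SHIFTS)
  expect_equal(dim(bands)[3], 7L)
  # exact lookup is bit-identical to the cube slice
  axis <- attr(cube, "axis")
  b2848 <- sample_bands(cube, 2848)
  expect_identical(as.vector(as_bare_array(b2848)[, , 1]),
                   as.vector(as_bare_array(cube)[, , which(axis == 2848)]))
  # 2845 on the 4 cm^-1 grid: nearest is 2844; 2846 is equidistant and
  # resolves to the lower shift 2844
  expect_identical(as.vector(as_bare_array(sample_bands(cube, 2845))),
                   as.vector(as_bare_array(cube)[, , which(axis == 2844)]))
  expect_identical(as.vector(as_bare_array(sample_bands(cube, 2846))),
                   as.vector(as_bare_array(cube)[, , which(axis == 2844)]))
  expect_error(sample_bands(cube, 2700), "outside")
})

test_that("H&E renders: style transform, artifact gating, contrast separation", {
  mask <- generate_tissue_mask(3, c(96, 96), "low", 3)
  ff <- render_he(mask, "FF_HE", seed = 9)
  ffpe <- render_he(mask, "FFPE_HE", seed = 9)
  # artifact-free FF and FFPE differ only by the global style transform
  expect_equal(as_bare_array(ffpe),
               as_bare_array(srstain:::.ffpe_style(as_bare_array(ff))),
               tolerance = 1e-12)
  expect_error(render_he(mask, "FFPE_HE",
                         artifact_config("freezing"), seed = 1),
               "artifact-free")
  # style separation: FFPE contrast exceeds FF for every seed
  for (s in 1:5) {
    f <- render_he(mask, "FF_HE", seed = s)
    p <- render_he(mask, "FFPE_HE", seed = s)
    for (k in 1:3) expect_gt(sd(p[, , k]), sd(f[, , k]))
  }
})

test_that("all four FF artifact kinds are selectable and knife cut brightens a streak", {
  mask <- generate_tissue_mask(3, c(96, 96), "low", 3)
  all4 <- render_he(mask, "FF_HE",
                    artifact_config(c("staining", "freezing", "knife_cut",
                                      "blurring")), seed = 2)
  meta <- attr(all4, "artifact_meta")
  expect_setequal(meta$kinds, c("staining", "freezing", "knife_cut",
                                "blurring"))
  expect_length(meta$freezing_holes, 3)
  # knife cut alone: one straight streak, brighter than local background
  kc <- render_he(mask, "FF_HE", artifact_config("knife_cut"), seed = 5)
  base <- render_he(mask, "FF_HE", seed = 5)
  line <- attr(kc, "artifact_meta")$knife_line
  yy <- matrix(seq_len(96), 96, 96)
  xx <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  dist <- abs((yy - line[["cy"]]) * cos(line[["theta"]]) +
                (xx - line[["cx"]]) * sin(line[["theta"]]))
  on_line <- dist <= line[["width"]] / 2
  near <- dist > line[["width"]] & dist < 4 * line[["width"]]
  lum <- (kc[, , 1] + kc[, , 2] + kc[, , 3]) / 3
  expect_gt(mean(lum[on_line]), mean(lum[near]))
  expect_gt(mean(lum[on_line]) - mean(lum[near]),
            0.5 * line[["contrast"]] * (1 - mean(lum[near])))
  # pixels off the streak are untouched
  expect_equal(kc[, , 1][dist > 2 * line[["width"]]],
               base[, , 1][dist > 2 * line[["width"]]])
})

test_that("multi-depth stacks morph smoothly and can grow a tumour at depth", {
  st <- generate_stack(11, c(20, 30), shape = c(96, 96))
  expect_length(st, 2)
  expect_equal(vapply(st, function(s) s$meta$depth_um, numeric(1)),
               c(20, 30))
  # adjacent planes are similar but not identical
  expect_false(identical(st[[1]]$mask, st[[2]]$mask))
  agree <- mean(unclass(st[[1]]$mask) == unclass(st[[2]]$mask))
  expect_gt(agree, 0.8)
  # zero decorrelation freezes the morphology
  st0 <- generate_stack(11, c(0, 20, 40), decorrelation = 0,
                        shape = c(96, 96))
  expect_identical(st0[[1]]$mask, st0[[2]]$mask)
  expect_identical(st0[[1]]$mask, st0[[3]]$mask)
  # tumour appears only at and beyond the onset depth
  stt <- generate_stack(12, c(0, 20, 40), shape = c(96, 96),
                        tumor_onset_um = 20)
  highs <- vapply(stt, function(s) s$meta$n_high_glands, integer(1))
  expect_equal(highs, c(0L, 2L, 2L))
  epi <- vapply(stt, function(s) class_counts(s$mask)[["epithelium"]],
                integer(1))
  expect_gt(epi[2], epi[1])
  expect_error(generate_stack(1, numeric(0)), "nonempty")
  expect_error(generate_stack(1, c(30, 20)), "nondecreasing")
})

test_that("datasets on disk are byte-identical across regeneration", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  man1 <- generate_dataset(4, d1, seed = 3,
                           grade_mix = c(low = 2, moderate = 1, high = 1),
                           shape = c(64, 64), gland_count = 2)
  man2 <- generate_dataset(4, d2, seed = 3,
                           grade_mix = c(low = 2, moderate = 1, high = 1),
                           shape = c(64, 64), gland_count = 2)
  expect_equal(man1$grade_counts, list(high = 1L, low = 2L, moderate = 1L))
  files <- list.files(d1, recursive = TRUE)
  expect_true(all(file.path(d2, files) %in%
                    file.path(d2, list.files(d2, recursive = TRUE))))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("phantom samples regenerate bit-identically from their seed", {
  s1 <- generate_phantom_sample(21, shape = c(64, 64))
  s2 <- generate_phantom_sample(21, shape = c(64, 64))
  expect_identical(s1, s2)
})
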