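# Registration, resampling, tiling, augmentation, two-colour rendering.

test_that("upsample2x doubles size with corner-aligned bilinear values", {
  const <- matrix(0.7, 5, 5)
  up <- upsample2x(const)
  expect_equal(dim(up), c(10L, 10L))
  expect_true(all(up == 0.7))
  ramp <- matrix(rep(seq(0, 1, length.out = 8), each = 6), 6, 8)
  upr <- upsample2x(ramp)
  # even output columns coincide with source pixels
  expect_equal(upr[1, seq(1, 15, 2)], ramp[1, ])
  # odd columns are midpoints
  expect_equal(upr[1, 2], (ramp[1, 1] + ramp[1, 2]) / 2)
  arr <- array(runif(100 * 100 * 3), c(100, 100, 3))
  expect_equal(dim(upsample2x(arr)), c(200L, 200L, 3L))
  expect_error(upsample2x(matrix(1, 1, 5)), "at least 2 x 2")
})

test_that("affine estimation is exact on consistent points and rejects degenerate input", {
  pts <- cbind(c(0, 10, 0, 10, 5, 3), c(0, 0, 10, 10, 5, 8))
  A_id <- estimate_affine(pts, pts)
  expect_equal(unclass(A_id), cbind(diag(2), c(0, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  th <- 10 * pi / 180
  A_true <- cbind(1.1 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                  c(5, -3))
  fixed <- t(A_true %*% rbind(t(pts), 1))
  A_est <- estimate_affine(pts, fixed)
  expect_lt(max(abs(unclass(A_est) - A_true)), 1e-6)
  expect_lt(attr(A_est, "rmse"), 1e-6)
  expect_error(estimate_affine(pts[1:2, ], fixed[1:2, ]), "at least 3")
  coll <- cbind(1:3, 2 * (1:3))
  expect_error(estimate_affine(coll, coll), "collinear")
})

test_that("warp: identity, integer translation, and composition", {
  img <- matrix(runif(30 * 30), 30, 30)
  A_id <- structure(cbind(diag(2), c(0, 0)), class = "affine_transform")
  expect_equal(warp(img, A_id), img, tolerance = 1e-12)
  A_tr <- structure(cbind(diag(2), c(3, -2)), class = "affine_transform")
  w <- warp(img, A_tr)
  # moving (x, y) maps to (x+3, y-2): output pixel (r, c) = input (r+2, c-3)
  expect_equal(w[1:28, 4:30], img[3:30, 1:27], tolerance = 1e-12)
  # composition on a smooth image
  smooth <- outer(seq(0, 1, length.out = 40), seq(0, 1, length.out = 40),
                  function(a, b) sin(3 * a) + cos(2 * b))
  th <- 5 * pi / 180
  A <- structure(cbind(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                       c(1, 0)), class = "affine_transform")
  B <- structure(cbind(diag(2) * 1.05, c(-1, 2)), class = "affine_transform")
  BA <- structure(cbind(unclass(B)[, 1:2] %*% unclass(A)[, 1:2],
                        unclass(B)[, 1:2] %*% unclass(A)[, 3] +
                          unclass(B)[, 3]),
                  class = "affine_transform")
  two_step <- warp(warp(smooth, A), B)
  one_step <- warp(smooth, BA)
  interior <- 8:32
  expect_lt(median(abs(two_step[interior, interior] -
                         one_step[interior, interior])), 0.02)
})

test_that("tiling emits fully in-bounds aligned patch pairs and untiles exactly", {
  srs <- array(runif(200 * 200 * 2), c(200, 200, 2))
  he <- array(runif(200 * 200 * 3), c(200, 200, 3))
  p1 <- tile_patches(srs[1:100, 1:100, , drop = FALSE],
                     he[1:100, 1:100, , drop = FALSE], size = 100)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$origin, c(row = 0, col = 0))
  p4 <- tile_patches(srs, he, size = 100, stride = 100)
  expect_length(p4, 4)
  for (p in p4) {
    expect_true(all(p$origin + 100 <= c(200, 200)))
    expect_equal(dim(p$srs_patch)[1:2], c(100L, 100L))
  }
  back <- untile_patches(p4, c(200, 200), "he_patch")
  expect_equal(back, he, tolerance = 1e-15)
  expect_warning(empty <- tile_patches(srs[1:50, 1:50, , drop = FALSE],
                                       he[1:50, 1:50, , drop = FALSE],
                                       size = 100),
                 "smaller than")
  expect_length(empty, 0)
})

test_that("augmentation crops to 384 with shared geometry and is seed-deterministic", {
  pr <- structure(list(
    srs_patch = array(runif(500 * 500 * 2), c(500, 500, 2)),
    he_patch = array(runif(500 * 500 * 3), c(500, 500, 3)),
    origin = c(0, 0), source_id = "t"
  ), class = "patch_record")
  a1 <- augment_patch(pr, crop = 384, seed = 42)
  a2 <- augment_patch(pr, crop = 384, seed = 42)
  expect_equal(dim(a1$srs_patch)[1:2], c(384L, 384L))
  expect_equal(dim(a1$he_patch)[1:2], c(384L, 384L))
  expect_identical(a1, a2)
  expect_identical(attr(a1, "crop_offset"), attr(a2, "crop_offset"))
  # geometry is shared: disabling the affine, both members come from the
  # same offset
  a3 <- augment_patch(pr, crop = 384, seed = 7, rotation_deg = 0,
                      scale_range = c(1, 1), shear_deg = 0)
  off <- attr(a3, "crop_offset")
  expect_equal(a3$srs_patch,
               pr$srs_patch[(off[1] + 1):(off[1] + 384),
                            (off[2] + 1):(off[2] + 384), , drop = FALSE])
  expect_equal(a3$he_patch,
               pr$he_patch[(off[1] + 1):(off[1] + 384),
                           (off[2] + 1):(off[2] + 384), , drop = FALSE])
  expect_error(augment_patch(pr, crop = 600), "crop larger")
})

test_that("two-colour rendering follows the dual-frequency convention", {
  H <- 8; W <- 8
  s <- array(0, c(H, W, 2))
  s[, , 1] <- 0.4  # 2847
  s[, , 2] <- 0.4  # 2933
  b <- band_image(s, c(2847, 2933))
  tc <- two_color(b)
  expect_true(all(tc[, , 3] == 0))  # equal bands: no blue
  expect_true(all(tc[, , 1] == 0))  # red identically zero
  # lipid-like pixels (2847 > 2933) are green, not blue
  lib <- make_spectral_library(1)
  mask <- generate_tissue_mask(6, c(64, 64), "low", 2,
                               ld_area_fraction = 0.05)
  cube <- render_cube(mask, lib, noise_sd = 0, seed = 1)
  tc2 <- two_color(sample_bands(cube))
  ld <- unclass(mask) == MASK_CLASSES[["lipid_droplet"]]
  expect_true(all(tc2[, , 2][ld] > tc2[, , 3][ld]))
  expect_error(two_color(band_image(s, c(2847, 2960))), "2933")
})
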