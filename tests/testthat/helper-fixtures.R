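# Shared fixtures, all generated in code at test time.

# A small noiseless cube whose pixel spectra are positive mixtures of three
# Gaussian basis spectra with well-separated peaks. Used by the band
# selection tests: three bands near the basis peaks determine every
# spectrum exactly.
make_basis_cube <- function(H = 40, W = 40, seed = 1,
                            peaks = c(2848, 2932, 3060)) {
  axis <- wavenumber_axis()
  basis <- sapply(peaks, function(p) exp(-(axis - p)^2 / (2 * 16^2)))
  mix <- srstain:::with_seed(seed, matrix(runif(H * W * 3, 0.1, 1), H * W, 3))
  vals <- array(mix %*% t(basis), c(H, W, length(axis)))
  list(cube = srs_cube(vals, axis), peaks = peaks, basis = basis, mix = mix)
}

# Tiny paired phantom patches for training smokes.
make_training_pairs <- function(n = 8, size = 64, seed = 1,
                                noise_sd = 0.01) {
  lib <- make_spectral_library(seed)
  gen_size <- max(size, 64)  # the mask generator needs >= 64 px
  lapply(seq_len(n), function(i) {
    s <- generate_phantom_sample(seed + i, shape = c(gen_size, gen_size),
                                 grade_class = "low", gland_count = 2,
                                 ld_area_fraction = 0.02,
                                 noise_sd = noise_sd, library = lib)
    # scale SRS bands to roughly [0, 1] for the network input
    x <- as_bare_array(s$bands)
    x <- x / max(x)
    he <- as_bare_array(s$ff_he)
    list(srs = x[seq_len(size), seq_len(size), , drop = FALSE],
         he = he[seq_len(size), seq_len(size), , drop = FALSE])
  })
}

# Brute-force Fleiss kappa by explicit rater-pair enumeration per item and
# category marginals; the independent oracle for the closed form.
brute_force_kappa <- function(ratings, categories = sort(unique(as.vector(ratings)))) {
  N <- nrow(ratings); r <- ncol(ratings)
  agree <- numeric(N)
  for (i in seq_len(N)) {
    pairs <- 0; hits <- 0
    for (a in seq_len(r - 1)) {
      for (b in (a + 1):r) {
        pairs <- pairs + 1
        hits <- hits + (ratings[i, a] == ratings[i, b])
      }
    }
    agree[i] <- hits / pairs
  }
  Pbar <- mean(agree)
  pj <- vapply(categories, function(cat) mean(ratings == cat), numeric(1))
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
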