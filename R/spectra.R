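# Discrete-frequency band selection by spectral reconstruction.
#
# The idea: if a small set of Raman shifts suffices to reconstruct the full
# CH-stretching spectrum of every pixel by linear regression, imaging only
# those shifts loses little chemical information. Reconstruction quality is
# scored on held-out pixels so that noise cannot make a selection look
# trivially good; bands are then chosen by greedy forward selection on that
# held-out error.
#
# All candidate evaluations reuse precomputed Gram matrices (crossproducts
# of the pixel matrix), which makes exhaustive small-k searches cheap enough
# to serve as an oracle for the greedy path.

# Pixel matrix (n x B) of a cube, optionally a seeded subsample of rows.
.cube_pixels <- function(cube, max_pixels, seed) {
  x <- as_bare_array(cube)
  n <- dim(x)[1] * dim(x)[2]
  X <- matrix(x, n, dim(x)[3])
  if (n > max_pixels) {
    keep <- with_seed(seed, sample.int(n, max_pixels))
    X <- X[keep, , drop = FALSE]
  }
  X
}

# Seeded train/holdout split of n rows.
.pixel_split <- function(n, holdout_fraction, seed) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie strictly between 0 and 1")
  }
  hold <- with_seed(seed + 1L, sample.int(n, max(1, round(n * holdout_fraction))))
  list(train = setdiff(seq_len(n), hold), hold = hold)
}

# Gram-matrix bundle for fast repeated subset regression. A = [1, X].
.gram_bundle <- function(X, split) {
  At <- cbind(1, X[split$train, , drop = FALSE])
  Ah <- cbind(1, X[split$hold, , drop = FALSE])
  Yt <- X[split$train, , drop = FALSE]
  Yh <- X[split$hold, , drop = FALSE]
  list(
    Gt = crossprod(At), Ct = crossprod(At, Yt),
    Gh = crossprod(Ah), Ch = crossprod(Ah, Yh),
    yh2 = sum(Yh^2), nh = nrow(Yh), B = ncol(X),
    col_mean_train = colMeans(Yt),
    train_var = apply(Yt, 2, stats::var),
    signal_mse = sum(Yh^2) / (nrow(Yh) * ncol(X))
  )
}

# Held-out mean squared reconstruction error for band subset `sel`
# (1-based band indices); uses only the Gram matrices.
.holdout_mse <- function(g, sel) {
  ii <- c(1L, sel + 1L)
  qg <- qr(g$Gt[ii, ii, drop = FALSE])
  beta <- qr.coef(qg, g$Ct[ii, , drop = FALSE])
  beta[is.na(beta)] <- 0
  # ||Yh - Ah beta||^2 expanded through the holdout Grams
  res <- g$yh2 - 2 * sum(beta * g$Ch[ii, , drop = FALSE]) +
    sum(beta * (g$Gh[ii, ii, drop = FALSE] %*% beta))
  max(res, 0) / (g$nh * g$B)
}

#' Fit a spectral reconstruction model for a set of bands
#'
#' Ordinary least squares, per output band, of the full hyperspectral
#' intensity on the selected-band intensities plus an intercept, using a
#' seeded pixel split. `r2` and `mse` are computed on the held-out pixels.
#'
#' @param cube An [srs_cube()].
#' @param selected_shifts Raman shifts to regress on; all must be on the
#'   cube axis. Duplicates are an error (rank-deficient design).
#' @param holdout_fraction Fraction of pixels held out (default 0.25).
#' @param seed Split seed.
#' @param max_pixels Cap on pixels used (seeded subsample beyond this).
#' @return A `reconstruction_model`: `selected_shifts`, `weights`
#'   ((k+1) x B matrix, intercept row first), `r2`, `mse`, bookkeeping.
#' @export
fit_reconstruction <- function(cube, selected_shifts, holdout_fraction = 0.25,
                               seed = 1, max_pixels = 20000) {
  axis <- attr(cube, "axis")
  if (length(selected_shifts) == 0) stop("selected_shifts must be nonempty")
  dup <- unique(selected_shifts[duplicated(selected_shifts)])
  if (length(dup)) {
    stop("duplicate bands make the design rank-deficient: ",
         paste(dup, collapse = ", "))
  }
  sel <- vapply(selected_shifts, function(f) {
    i <- which(axis == f)
    if (length(i) != 1L) stop(sprintf("shift %g is not on the cube axis", f))
    i
  }, integer(1))
  X <- .cube_pixels(cube, max_pixels, seed)
  split <- .pixel_split(nrow(X), holdout_fraction, seed)
  At <- cbind(`(Intercept)` = 1, X[split$train, sel, drop = FALSE])
  # collinear designs (e.g. a low-rank cube) take the pivoted least-squares
  # solution; only duplicated bands are an error (caught above)
  beta <- qr.coef(qr(At), X[split$train, , drop = FALSE])
  beta[is.na(beta)] <- 0
  Ah <- cbind(1, X[split$hold, sel, drop = FALSE])
  Yh <- X[split$hold, , drop = FALSE]
  resid <- Yh - Ah %*% beta
  mse <- mean(resid^2)
  ss_res <- sum(resid^2)
  ss_tot <- sum(sweep(Yh, 2, colMeans(X[split$train, , drop = FALSE]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  rownames(beta) <- c("(Intercept)", as.character(selected_shifts))
  colnames(beta) <- as.character(axis)
  structure(list(
    selected_shifts = as.numeric(selected_shifts), weights = beta,
    r2 = r2, mse = mse, holdout_fraction = holdout_fraction, seed = seed,
    n_train = length(split$train), n_holdout = length(split$hold),
    axis = as.numeric(axis)
  ), class = "reconstruction_model")
}

#' @export
print.reconstruction_model <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_model> k = %d bands (%s), holdout R^2 = %.4f, mse = %.3g\n",
    length(x$selected_shifts), paste(x$selected_shifts, collapse = ", "),
    x$r2, x$mse
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.reconstruction_model <- function(x, ...) {
  data.frame(k = length(x$selected_shifts), r2 = x$r2, mse = x$mse,
             n_train = x$n_train, n_holdout = x$n_holdout)
}

#' @exportS3Method generics::tidy
tidy.reconstruction_model <- function(x, ...) {
  path <- attr(x, "mse_path")
  if (is.null(path)) {
    data.frame(order = seq_along(x$selected_shifts),
               shift_cm1 = x$selected_shifts, mse = NA_real_)
  } else {
    data.frame(order = seq_along(x$selected_shifts),
               shift_cm1 = x$selected_shifts, mse = path)
  }
}

#' Greedy forward band selection
#'
#' Starting from the empty set, repeatedly adds the candidate band that
#' minimises held-out reconstruction error given the bands already chosen.
#' Errors equal within numerical resolution (relative to the held-out
#' signal power) are ties: the higher-variance (higher-signal) band wins --
#' on degenerate noiseless data this lands selection on the dominant
#' spectral peaks -- and any remaining exact tie resolves to the lower
#' shift. The train/holdout split is drawn once and reused for every
#' evaluation, so the path is deterministic given the seed.
#'
#' @param cube An [srs_cube()].
#' @param k Number of bands to select (1 <= k <= number of candidates).
#' @param candidate_shifts Candidate shifts (default: the whole axis).
#' @param seed Split seed.
#' @param holdout_fraction,max_pixels As [fit_reconstruction()].
#' @return The final `reconstruction_model`, with `selected_shifts` in
#'   selection order and attribute `mse_path` (held-out mse after each
#'   addition).
#' @export
greedy_select <- function(cube, k, candidate_shifts = NULL, seed = 1,
                          holdout_fraction = 0.25, max_pixels = 20000) {
  axis <- attr(cube, "axis")
  if (is.null(candidate_shifts)) candidate_shifts <- axis
  candidate_shifts <- sort(unique(as.numeric(candidate_shifts)))
  cand <- vapply(candidate_shifts, function(f) {
    i <- which(axis == f)
    if (length(i) != 1L) stop(sprintf("candidate %g is not on the cube axis", f))
    i
  }, integer(1))
  if (k < 1 || k > length(cand)) {
    stop(sprintf("k must lie in [1, %d]", length(cand)))
  }
  X <- .cube_pixels(cube, max_pixels, seed)
  split <- .pixel_split(nrow(X), holdout_fraction, seed)
  g <- .gram_bundle(X, split)
  chosen <- integer(0)
  mse_path <- numeric(0)
  for (step in seq_len(k)) {
    remaining <- setdiff(cand, chosen)
    mses <- vapply(remaining, function(b) .holdout_mse(g, c(chosen, b)),
                   numeric(1))
    if (!any(is.finite(mses))) {
      best_band <- remaining[1]
      best <- mses[1]
    } else {
      # candidates within numerical resolution of the minimum (relative to
      # the held-out signal power) are ties: prefer the higher-variance
      # (higher-signal) band, then -- candidates being in ascending shift
      # order -- the lower shift
      tol <- 1e-9 * max(g$signal_mse, .Machine$double.xmin)
      ties <- which(mses <= min(mses, na.rm = TRUE) + tol)
      best_idx <- ties[which.max(g$train_var[remaining[ties]])]
      best_band <- remaining[best_idx]
      best <- mses[best_idx]
    }
    chosen <- c(chosen, best_band)
    mse_path <- c(mse_path, best)
  }
  model <- fit_reconstruction(cube, axis[chosen],
                              holdout_fraction = holdout_fraction,
                              seed = seed, max_pixels = max_pixels)
  attr(model, "mse_path") <- mse_path
  model
}

#' Exhaustive band-subset search
#'
#' Evaluates every size-`k` subset of the candidates on the same held-out
#' error as [greedy_select()] and returns the best. Feasible for small `k`
#' (all 3-subsets of a 77-band axis take a few seconds); used as the
#' reference the greedy path is compared against.
#'
#' @inheritParams greedy_select
#' @return A `reconstruction_model` for the best subset, with attribute
#'   `best_mse` (the Gram-computed held-out mse).
#' @export
exhaustive_select <- function(cube, k, candidate_shifts = NULL, seed = 1,
                              holdout_fraction = 0.25, max_pixels = 20000) {
  axis <- attr(cube, "axis")
  if (is.null(candidate_shifts)) candidate_shifts <- axis
  candidate_shifts <- sort(unique(as.numeric(candidate_shifts)))
  cand <- vapply(candidate_shifts, function(f) which(axis == f), integer(1))
  if (k < 1 || k > length(cand)) stop("k exceeds candidates")
  X <- .cube_pixels(cube, max_pixels, seed)
  split <- .pixel_split(nrow(X), holdout_fraction, seed)
  g <- .gram_bundle(X, split)
  combos <- utils::combn(cand, k)
  mses <- vapply(seq_len(ncol(combos)), function(j) {
    .holdout_mse(g, combos[, j])
  }, numeric(1))
  tol <- 1e-9 * max(g$signal_mse, .Machine$double.xmin)
  ties <- which(mses <= min(mses) + tol)
  # same degenerate-tie rule as the greedy path: highest total band
  # variance, then the first (lexicographically lowest) subset
  tot_var <- vapply(ties, function(j) sum(g$train_var[combos[, j]]),
                    numeric(1))
  jbest <- ties[which.max(tot_var)]
  best <- mses[jbest]
  best_sel <- combos[, jbest]
  model <- fit_reconstruction(cube, axis[best_sel],
                              holdout_fraction = holdout_fraction,
                              seed = seed, max_pixels = max_pixels)
  attr(model, "best_mse") <- best
  model
}
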