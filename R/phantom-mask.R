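# Glandular tissue-mask generator.
#
# A phantom section is a stroma background carrying a configurable number of
# prostate-like glands: a lumen core surrounded by an epithelial ring studded
# with nuclei. The clinical-concern class controls architecture the way
# grading does: low-concern tissue has open lumens, moderate concern has
# crowded glands with small lumens, and high concern has fused epithelial
# sheets without lumens. Lipid droplets are planted as small disks inside the
# epithelium to reach a requested area fraction.
#
# Mask construction is split into parameter sampling (gland_params) and
# deterministic rasterisation (build_mask), so that multi-depth stacks can
# morph one parameter set smoothly across planes.

.grade_presets <- list(
  low = list(lumen_frac = 0.55, radius_scale = 1.00, crowding = 1.00),
  moderate = list(lumen_frac = 0.22, radius_scale = 0.85, crowding = 0.70),
  high = list(lumen_frac = 0.00, radius_scale = 1.25, crowding = 0.55)
)

# Sample gland centres/radii for one section. Centres sit on a jittered grid
# so glands spread over the section; `crowding` < 1 pulls them closer.
gland_params <- function(seed, shape, grade_class, gland_count) {
  preset <- .grade_presets[[grade_class]]
  if (is.null(preset)) stop("grade_class must be low, moderate or high")
  with_seed(seed, {
    H <- shape[1]; W <- shape[2]
    if (gland_count == 0) {
      return(list(glands = list(), grade_class = grade_class, shape = shape))
    }
    ngrid <- ceiling(sqrt(gland_count))
    cy <- (rep(seq_len(ngrid), each = ngrid) - 0.5) / ngrid * H
    cx <- (rep(seq_len(ngrid), times = ngrid) - 0.5) / ngrid * W
    keep <- sample(seq_along(cy), gland_count)
    r0 <- 0.32 * min(H, W) / ngrid * preset$radius_scale
    glands <- lapply(seq_len(gland_count), function(i) {
      k <- keep[i]
      jit <- (1 - preset$crowding) * 0.25 * min(H, W) / ngrid
      list(
        cy = cy[k] + runif(1, -jit - 1, jit + 1),
        cx = cx[k] + runif(1, -jit - 1, jit + 1),
        r = r0 * runif(1, 0.8, 1.2),
        lumen_frac = preset$lumen_frac * runif(1, 0.85, 1.15),
        grade = grade_class,
        n_nuclei = NA_integer_,  # filled at rasterisation from the ring area
        angle0 = runif(1, 0, 2 * pi),
        drift = runif(2, -1, 1)  # unit-free per-gland drift direction
      )
    })
    list(glands = glands, grade_class = grade_class, shape = shape)
  })
}

# Rasterise gland parameters into a label mask (no droplets yet). The outer
# 2-pixel frame is background (slide edge); everything else starts as stroma.
build_mask <- function(params, nuclei_seed = 1) {
  H <- params$shape[1]; W <- params$shape[2]
  lab <- matrix(MASK_CLASSES[["stroma"]], H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (g in params$glands) {
    d2 <- (yy - g$cy)^2 + (xx - g$cx)^2
    inside <- d2 <= g$r^2
    lab[inside] <- MASK_CLASSES[["epithelium"]]
    if (g$lumen_frac > 0) {
      lab[d2 <= (g$r * g$lumen_frac)^2] <- MASK_CLASSES[["lumen"]]
    }
  }
  # nuclei: small disks placed on each gland's epithelial ring
  lab <- with_seed(nuclei_seed, {
    for (g in params$glands) {
      ring_r <- g$r * (1 + g$lumen_frac) / 2
      n_nuc <- max(3L, round(2 * pi * ring_r / 6))
      ang <- g$angle0 + seq(0, 2 * pi, length.out = n_nuc + 1)[-1] +
        runif(n_nuc, -0.1, 0.1)
      ny <- g$cy + ring_r * sin(ang)
      nx <- g$cx + ring_r * cos(ang)
      for (j in seq_len(n_nuc)) {
        sel <- (yy - ny[j])^2 + (xx - nx[j])^2 <= 1.5^2
        sel <- sel & lab == MASK_CLASSES[["epithelium"]]
        lab[sel] <- MASK_CLASSES[["nucleus"]]
      }
    }
    lab
  })
  lab[c(1:2, H - 1, H), ] <- MASK_CLASSES[["background"]]
  lab[, c(1:2, W - 1, W)] <- MASK_CLASSES[["background"]]
  label_mask(lab)
}

# Plant lipid-droplet disks inside the epithelium so that the emitted mask
# satisfies (droplet pixels) / (epithelium pixels) ~= fraction. Solving
# L = f * E0 / (1 + f) for the droplet pixel budget, where E0 is the
# epithelial area before planting, gives exactly that ratio after L
# epithelium pixels are converted. The last droplets are shrunk to single
# pixels so the budget is hit to within a few pixels.
plant_droplets <- function(mask, fraction, seed, radius_range = c(1, 3)) {
  if (fraction < 0 || fraction > 0.2) {
    stop("ld_area_fraction must lie in [0, 0.2]")
  }
  if (fraction == 0) return(structure(mask, ld_planted = 0L))
  lab <- unclass(mask)
  epi <- which(lab == MASK_CLASSES[["epithelium"]])
  E0 <- length(epi)
  if (E0 == 0) {
    stop(sprintf(
      "ld_area_fraction %.4g unattainable: no epithelium in mask (achievable maximum 0)",
      fraction
    ))
  }
  target <- max(1L, round(fraction * E0 / (1 + fraction)))
  H <- nrow(lab); W <- ncol(lab)
  lab <- with_seed(seed, {
    planted <- 0L
    guard <- 0L
    while (planted < target && guard < 50 * target) {
      guard <- guard + 1L
      remaining <- target - planted
      centre <- epi[sample.int(length(epi), 1)]
      cy <- ((centre - 1) %% H) + 1
      cx <- ((centre - 1) %/% H) + 1
      r <- if (remaining >= 13) runif(1, radius_range[1], radius_range[2])
           else if (remaining >= 5) 1 else 0
      ys <- max(1, cy - ceiling(r)):min(H, cy + ceiling(r))
      xs <- max(1, cx - ceiling(r)):min(W, cx + ceiling(r))
      sel <- expand.grid(y = ys, x = xs)
      sel <- sel[(sel$y - cy)^2 + (sel$x - cx)^2 <= r^2, , drop = FALSE]
      idx <- sel$y + (sel$x - 1) * H
      idx <- idx[lab[idx] == MASK_CLASSES[["epithelium"]]]
      idx <- head(idx, remaining)
      lab[idx] <- MASK_CLASSES[["lipid_droplet"]]
      planted <- planted + length(idx)
    }
    if (planted < target * 0.9) {
      stop(sprintf(
        "ld_area_fraction %.4g unattainable: epithelium area %d allows at most %.4g",
        fraction, E0, planted / (E0 - planted)
      ))
    }
    lab
  })
  structure(label_mask(lab), ld_planted = sum(lab == MASK_CLASSES[["lipid_droplet"]]))
}

#' Generate a synthetic glandular tissue mask
#'
#' Draws a stroma background with `gland_count` glands whose architecture
#' follows the clinical-concern class (`low` = open lumens, `moderate` =
#' crowded small lumens, `high` = fused epithelial sheets without lumens),
#' nuclei dotted along each epithelial ring, and lipid-droplet disks planted
#' inside the epithelium. The droplet budget is chosen so that droplet pixels
#' divided by epithelium pixels in the emitted mask equals
#' `ld_area_fraction` to within about 10 percent relative.
#'
#' @param seed Integer seed; identical seeds give bit-identical masks.
#' @param shape `c(H, W)`, at least 64 x 64.
#' @param grade_class `"low"`, `"moderate"` or `"high"`.
#' @param gland_count Number of glands (0 gives pure stroma plus the
#'   background border).
#' @param ld_area_fraction Target droplet/epithelium pixel ratio, in
#'   \[0, 0.2\]. An unattainable request errors, naming the achievable
#'   maximum.
#' @param ld_radius_range Droplet radius range in pixels.
#' @return A [label_mask()] with attribute `ld_planted` (droplet pixel
#'   count).
#' @export
generate_tissue_mask <- function(seed, shape = c(128, 128),
                                 grade_class = "low", gland_count = 4,
                                 ld_area_fraction = 0,
                                 ld_radius_range = c(1, 3)) {
  if (any(shape < 64)) stop("shape must be at least 64 x 64")
  params <- gland_params(seed, shape, grade_class, gland_count)
  mask <- build_mask(params, nuclei_seed = seed + 1L)
  plant_droplets(mask, ld_area_fraction, seed = seed + 2L,
                 radius_range = ld_radius_range)
}
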