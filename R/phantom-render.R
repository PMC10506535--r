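# Forward models turning a label mask into (a) a hyperspectral SRS cube and
# (b) FF / FFPE H&E renderings.
#
# The SRS model is deliberately simple: each pixel emits its class spectrum
# scaled by a smooth per-pixel brightness field, plus additive zero-mean
# Gaussian noise, optionally blurred, clipped at zero. It is not a physical
# Raman cross-section model; it preserves exactly the band ratios that the
# downstream droplet statistic and the virtual-staining networks consume.

# Smooth multiplicative field in [1-amp, 1+amp]: white noise blurred with a
# large Gaussian kernel and rescaled.
smooth_field <- function(shape, amp, sigma, seed) {
  # gblur's kernel must fit inside the image
  sigma <- min(sigma, (min(shape) - 2) / 7)
  with_seed(seed, {
    z <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    z <- as.matrix(EBImage::gblur(z, sigma = sigma))
    rng <- max(abs(z))
    if (rng == 0) rng <- 1
    1 + amp * z / rng
  })
}

#' Render a hyperspectral SRS cube from a label mask
#'
#' Per-pixel spectrum = class spectrum x per-pixel brightness, plus zero-mean
#' Gaussian noise, optional per-band Gaussian blur, clipped at zero. The
#' `background` and `lumen` classes (no tissue) emit a low flat baseline.
#'
#' @param mask A [label_mask()].
#' @param library A `spectral_library`; every tissue class present in the
#'   mask must have a spectrum (error otherwise).
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; the library spectra have maximum 1).
#' @param blur_sigma Spatial Gaussian blur sigma in pixels, 0 for none.
#' @param seed Seed controlling brightness field and noise.
#' @param brightness_amp Half-range of the smooth brightness field.
#' @param pixel_size_um,depth_um Metadata carried on the cube.
#' @return An [srs_cube()] with attribute `brightness` (the H x W field).
#' @export
render_cube <- function(mask, library, noise_sd = 0.01, blur_sigma = 0,
                        seed = 1, brightness_amp = 0.15,
                        pixel_size_um = 1, depth_um = 0) {
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  axis <- attr(library, "axis")
  B <- length(axis)
  H <- nrow(mask); W <- ncol(mask)
  class_to_spec <- list()
  empty_baseline <- rep(0.02, B)
  for (cls in names(MASK_CLASSES)) {
    code <- MASK_CLASSES[[cls]]
    if (!any(mask == code)) next
    spec <- switch(cls,
      background = empty_baseline,
      lumen = empty_baseline,
      stroma = library[["stroma"]],
      epithelium = library[["epithelium"]],
      nucleus = library[["nuclei"]],
      lipid_droplet = library[["lipid_droplet"]]
    )
    if (is.null(spec)) {
      stop(sprintf("mask class '%s' missing from spectral library", cls))
    }
    class_to_spec[[as.character(code)]] <- spec
  }
  spec_mat <- matrix(0, length(MASK_CLASSES), B)
  for (code in names(class_to_spec)) {
    spec_mat[as.integer(code) + 1L, ] <- class_to_spec[[code]]
  }
  bright <- smooth_field(c(H, W), brightness_amp, sigma = max(4, min(H, W) / 8),
                         seed = seed)
  vals <- spec_mat[as.vector(unclass(mask)) + 1L, , drop = FALSE] *
    as.vector(bright)
  cube <- array(vals, c(H, W, B))
  if (noise_sd > 0) {
    cube <- cube + with_seed(seed + 1L,
                             array(rnorm(H * W * B, 0, noise_sd), c(H, W, B)))
  }
  if (blur_sigma > 0) {
    for (b in seq_len(B)) {
      cube[, , b] <- as.matrix(EBImage::gblur(cube[, , b], sigma = blur_sigma))
    }
  }
  cube[cube < 0] <- 0
  out <- srs_cube(cube, axis, pixel_size_um = pixel_size_um,
                  depth_um = depth_um)
  attr(out, "brightness") <- bright
  out
}

#' Default discrete acquisition frequencies
#'
#' The seven Raman shifts used for discrete-frequency SRS acquisition:
#' 2847, 2879, 2902, 2933, 2960, 2979 and 3062 cm^-1.
#' @export
DEFAULT_BAND_SHIFTS <- c(2847, 2879, 2902, 2933, 2960, 2979, 3062)

#' Sample discrete-frequency bands from a hyperspectral cube
#'
#' Channel k of the result is the cube band whose axis entry is nearest to
#' `freqs[k]`; equidistant ties resolve to the lower shift. Channel names
#' record the requested shifts.
#'
#' @param cube An [srs_cube()].
#' @param freqs Requested Raman shifts, cm^-1; each must fall inside the
#'   axis range.
#' @return A [band_image()] with `freqs` as its channel shifts.
#' @export
sample_bands <- function(cube, freqs = DEFAULT_BAND_SHIFTS) {
  axis <- attr(cube, "axis")
  idx <- vapply(freqs, function(f) nearest_band(axis, f), integer(1))
  vals <- as_bare_array(cube)[, , idx, drop = FALSE]
  band_image(vals, freqs,
    pixel_size_um = attr(cube, "pixel_size_um"),
    depth_um = attr(cube, "depth_um")
  )
}

#' FF-artifact configuration
#'
#' Selects which fresh-frozen section artifacts to paint into an FF H&E
#' render and their severities. An empty `kinds` means artifact-free.
#'
#' @param kinds Character subset of `"staining"`, `"freezing"`,
#'   `"knife_cut"`, `"blurring"`.
#' @param staining_strength Amplitude of the smooth multiplicative stain
#'   unevenness field.
#' @param freezing_n Number of white elliptical freeze holes.
#' @param freezing_axes Ellipse semi-axis range, pixels.
#' @param knife_width Knife-cut streak width, pixels.
#' @param knife_contrast Brightening applied inside the streak: pixels move
#'   toward white by this fraction of their headroom.
#' @param blur_sigma,blur_radius Local blur patch: Gaussian sigma and patch
#'   radius in pixels.
#' @param seed Seed for artifact geometry (`NULL` = use the render seed).
#' @return An `artifact_config` list.
#' @export
artifact_config <- function(kinds = character(), staining_strength = 0.25,
                            freezing_n = 3, freezing_axes = c(5, 12),
                            knife_width = 3, knife_contrast = 0.35,
                            blur_sigma = 3, blur_radius = 20, seed = NULL) {
  bad <- setdiff(kinds, c("staining", "freezing", "knife_cut", "blurring"))
  if (length(bad)) stop("unknown artifact kinds: ", paste(bad, collapse = ", "))
  structure(list(
    kinds = kinds, staining_strength = staining_strength,
    freezing_n = freezing_n, freezing_axes = freezing_axes,
    knife_width = knife_width, knife_contrast = knife_contrast,
    blur_sigma = blur_sigma, blur_radius = blur_radius, seed = seed
  ), class = "artifact_config")
}

# H&E colour lookup per class (R, G, B in [0,1]). Hematoxylin blue-purple
# nuclei, eosin-pink stroma, slightly deeper pink epithelium, white lumen.
.he_colors <- rbind(
  background = c(0.96, 0.96, 0.97),
  stroma = c(0.93, 0.62, 0.73),
  epithelium = c(0.85, 0.52, 0.68),
  nucleus = c(0.36, 0.22, 0.56),
  lumen = c(0.97, 0.96, 0.97),
  lipid_droplet = c(0.93, 0.88, 0.83)
)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# FFPE global style transform: contrast about each channel's mean (so
# bright tissue does not saturate into the clip), then a saturation gain.
.ffpe_style <- function(img, contrast = 1.35, saturation = 1.15) {
  y <- img
  for (k in 1:3) {
    m <- mean(img[, , k])
    y[, , k] <- m + contrast * (img[, , k] - m)
  }
  gray <- (y[, , 1] + y[, , 2] + y[, , 3]) / 3
  for (k in 1:3) y[, , k] <- gray + saturation * (y[, , k] - gray)
  clamp01(y)
}

#' Render an H&E image from a label mask
#'
#' Deterministic per-class colour lookup (hematoxylin blue-purple nuclei,
#' eosin-pink stroma and cytoplasm, white lumen) modulated by a seeded
#' multiplicative texture field. The FFPE style applies a global
#' contrast/saturation boost on top of the FF base, so artifact-free FF and
#' FFPE renders of the same mask differ only by that transform. Fresh-frozen
#' artifacts (staining unevenness, freezing holes, knife-cut streak, local
#' blurring) can be painted into FF renders only; FFPE is defined
#' artifact-free here and requesting artifacts with it is an error.
#'
#' @param mask A [label_mask()].
#' @param style `"FF_HE"` or `"FFPE_HE"`.
#' @param artifacts An [artifact_config()].
#' @param seed Seed for texture (and artifact geometry unless the config
#'   carries its own seed).
#' @return An [rgb_image()] with attribute `artifact_meta` describing the
#'   painted artifacts.
#' @export
render_he <- function(mask, style = c("FF_HE", "FFPE_HE"),
                      artifacts = artifact_config(), seed = 1) {
  style <- match.arg(style)
  if (style == "FFPE_HE" && length(artifacts$kinds) > 0) {
    stop("FFPE renders are artifact-free; artifacts are FF-only")
  }
  H <- nrow(mask); W <- ncol(mask)
  cols <- .he_colors[match(as.vector(unclass(mask)), MASK_CLASSES), ,
                     drop = FALSE]
  img <- array(cols, c(H, W, 3))
  tex <- smooth_field(c(H, W), amp = 0.08, sigma = 3, seed = seed)
  for (k in 1:3) img[, , k] <- img[, , k] * tex
  img <- clamp01(img)
  meta <- list(kinds = artifacts$kinds)
  if (style == "FFPE_HE") {
    return(structure(rgb_image(.ffpe_style(img), "FFPE_HE"),
                     artifact_meta = meta))
  }
  aseed <- if (is.null(artifacts$seed)) seed + 100L else artifacts$seed
  img <- with_seed(aseed, {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    if ("staining" %in% artifacts$kinds) {
      f <- smooth_field(c(H, W), artifacts$staining_strength,
                        sigma = min(H, W) / 5, seed = aseed + 1L)
      for (k in 1:3) img[, , k] <- img[, , k] * f
      meta$staining_field_range <- range(f)
    }
    if ("freezing" %in% artifacts$kinds) {
      holes <- list()
      for (i in seq_len(artifacts$freezing_n)) {
        cy <- runif(1, H * 0.15, H * 0.85)
        cx <- runif(1, W * 0.15, W * 0.85)
        a <- runif(1, artifacts$freezing_axes[1], artifacts$freezing_axes[2])
        b <- runif(1, artifacts$freezing_axes[1], artifacts$freezing_axes[2])
        th <- runif(1, 0, pi)
        u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
        v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
        sel <- (u / a)^2 + (v / b)^2 <= 1
        for (k in 1:3) {
          ch <- img[, , k]
          ch[sel] <- 0.97
          img[, , k] <- ch
        }
        holes[[i]] <- c(cy = cy, cx = cx, a = a, b = b)
      }
      meta$freezing_holes <- holes
    }
    if ("knife_cut" %in% artifacts$kinds) {
      th <- runif(1, 0, pi)
      cy <- H / 2 + runif(1, -H / 6, H / 6)
      cx <- W / 2 + runif(1, -W / 6, W / 6)
      dist <- abs((yy - cy) * cos(th) + (xx - cx) * sin(th))
      sel <- dist <= artifacts$knife_width / 2
      for (k in 1:3) {
        ch <- img[, , k]
        ch[sel] <- ch[sel] + artifacts$knife_contrast * (1 - ch[sel])
        img[, , k] <- ch
      }
      meta$knife_line <- c(cy = cy, cx = cx, theta = th,
                            width = artifacts$knife_width,
                            contrast = artifacts$knife_contrast)
    }
    if ("blurring" %in% artifacts$kinds) {
      cy <- runif(1, H * 0.25, H * 0.75)
      cx <- runif(1, W * 0.25, W * 0.75)
      sel <- (yy - cy)^2 + (xx - cx)^2 <= artifacts$blur_radius^2
      for (k in 1:3) {
        blurred <- as.matrix(EBImage::gblur(img[, , k],
                                            sigma = artifacts$blur_sigma))
        ch <- img[, , k]
        ch[sel] <- blurred[sel]
        img[, , k] <- ch
      }
      meta$blur_patch <- c(cy = cy, cx = cx, radius = artifacts$blur_radius)
    }
    img
  })
  structure(rgb_image(clamp01(img), "FF_HE"), artifact_meta = meta)
}
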