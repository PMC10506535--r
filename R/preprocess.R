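# Registration, resampling, tiling and augmentation.
#
# Coordinate conventions, used everywhere in this file: 0-based (row, col),
# origin at the top-left pixel, half-open patch intervals. upsample2x uses
# the corner-aligned convention in which even output indices coincide with
# source pixels: y[2i] = x[i], y[2i+1] = (x[i] + x[i+1]) / 2, with the last
# odd index replicating the edge.

#' Bilinear 2x upsampling
#'
#' Doubles both spatial dimensions with corner-aligned bilinear
#' interpolation (even output rows/columns equal the source pixels exactly).
#' Works on matrices or H x W x C arrays (channels upsampled independently).
#'
#' @param image Matrix or 3-d array, H and W at least 2.
#' @return Array of size 2H x 2W (x C).
#' @export
upsample2x <- function(image) {
  up1 <- function(m) {
    H <- nrow(m); W <- ncol(m)
    if (H < 2 || W < 2) stop("image must be at least 2 x 2")
    rows <- matrix(0, 2 * H, W)
    rows[seq(1, 2 * H, 2), ] <- m
    mid <- (m[-H, , drop = FALSE] + m[-1, , drop = FALSE]) / 2
    rows[seq(2, 2 * H - 2, 2), ] <- mid
    rows[2 * H, ] <- m[H, ]
    out <- matrix(0, 2 * H, 2 * W)
    out[, seq(1, 2 * W, 2)] <- rows
    midc <- (rows[, -W, drop = FALSE] + rows[, -1, drop = FALSE]) / 2
    out[, seq(2, 2 * W - 2, 2)] <- midc
    out[, 2 * W] <- rows[, W]
    out
  }
  if (is.matrix(image)) return(up1(image))
  d <- dim(image)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- up1(image[, , k])
  attrs <- attributes(image)
  attrs$dim <- NULL
  for (nm in setdiff(names(attrs), c("dim", "dimnames"))) {
    attr(out, nm) <- attrs[[nm]]
  }
  out
}

#' Estimate an affine transform from control points
#'
#' Least-squares 2x3 affine mapping moving-image coordinates to fixed-image
#' coordinates from at least 3 non-collinear point pairs. Exact (residual
#' below 1e-6) on noiseless affine-consistent points.
#'
#' @param moving,fixed n x 2 matrices of (x, y) pixel coordinates, n >= 3.
#' @return An `affine_transform`: 2 x 3 matrix `A` such that
#'   `fixed ~ A %*% c(x, y, 1)`, with attribute `rmse`.
#' @export
estimate_affine <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) < 3 || nrow(fixed) != nrow(moving)) {
    stop("need at least 3 control-point pairs")
  }
  D <- cbind(moving, 1)
  if (qr(D)$rank < 3) stop("control points are collinear; affine is underdetermined")
  beta <- qr.coef(qr(D), fixed)  # 3 x 2
  A <- t(beta)                   # 2 x 3
  pred <- D %*% beta
  structure(A, rmse = sqrt(mean((pred - fixed)^2)),
            class = "affine_transform")
}

# Invert a 2x3 affine (for inverse-mapped warping).
.affine_invert <- function(A) {
  L <- A[, 1:2]
  if (abs(det(L)) < 1e-12) stop("affine transform is not invertible")
  Li <- solve(L)
  cbind(Li, -Li %*% A[, 3])
}

#' Warp an image through an affine transform
#'
#' Inverse-mapped bilinear warp: each output pixel looks up its preimage
#' under the transform and interpolates. Samples falling outside the source
#' are filled with the source median (avoids dark-border artifacts leaking
#' into training).
#'
#' @param image Matrix or H x W x C array.
#' @param transform An `affine_transform` (moving -> fixed); the output is
#'   on the fixed grid.
#' @param out_shape `c(H, W)` of the output (default: input shape).
#' @param fill Fill value (default: `median(image)`).
#' @return Warped array of size `out_shape` (x C).
#' @export
warp <- function(image, transform, out_shape = NULL, fill = NULL) {
  arr <- if (is.matrix(image)) array(image, c(dim(image), 1)) else image
  d <- dim(arr)
  if (is.null(out_shape)) out_shape <- d[1:2]
  if (is.null(fill)) fill <- median(arr)
  Ai <- .affine_invert(unclass(transform))
  # output pixel centres, 0-based (x = col, y = row)
  gx <- rep(seq_len(out_shape[2]) - 1, each = out_shape[1])
  gy <- rep(seq_len(out_shape[1]) - 1, times = out_shape[2])
  sx <- Ai[1, 1] * gx + Ai[1, 2] * gy + Ai[1, 3]
  sy <- Ai[2, 1] * gx + Ai[2, 2] * gy + Ai[2, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- sx >= 0 & sy >= 0 & sx <= d[2] - 1 & sy <= d[1] - 1
  # clamp corners for the interpolation reads; outside pixels overwritten
  xi0 <- pmin(pmax(x0, 0), d[2] - 1); yi0 <- pmin(pmax(y0, 0), d[1] - 1)
  xi1 <- pmin(xi0 + 1, d[2] - 1); yi1 <- pmin(yi0 + 1, d[1] - 1)
  out <- array(fill, c(out_shape, d[3]))
  for (k in seq_len(d[3])) {
    ch <- arr[, , k]
    v <- (1 - fx) * (1 - fy) * ch[cbind(yi0 + 1, xi0 + 1)] +
      fx * (1 - fy) * ch[cbind(yi0 + 1, xi1 + 1)] +
      (1 - fx) * fy * ch[cbind(yi1 + 1, xi0 + 1)] +
      fx * fy * ch[cbind(yi1 + 1, xi1 + 1)]
    v[!inside] <- fill
    out[, , k] <- v
  }
  if (is.matrix(image)) out[, , 1] else out
}

#' Tile co-registered SRS/H&E images into aligned patch pairs
#'
#' Cuts a regular grid of fully in-bounds patches from a co-registered
#' SRS band image and H&E image and records each patch's origin.
#'
#' @param srs H x W x K array (SRS bands).
#' @param he H x W x 3 array (H&E), same spatial extent.
#' @param size Patch side, pixels (default 500).
#' @param stride Grid stride, pixels (default `size`).
#' @param source_id Identifier recorded on every emitted patch.
#' @return List of `patch_record`: `srs_patch`, `he_patch`, `origin`
#'   (0-based `c(row, col)`), `source_id`. Images smaller than `size` give
#'   an empty list with a warning.
#' @export
tile_patches <- function(srs, he, size = 500, stride = size,
                         source_id = "image") {
  if (any(dim(srs)[1:2] != dim(he)[1:2])) {
    stop("srs and he must share H x W")
  }
  H <- dim(srs)[1]; W <- dim(srs)[2]
  if (H < size || W < size) {
    warning("image smaller than patch size; no patches emitted")
    return(list())
  }
  rows <- seq(0, H - size, by = stride)
  cols <- seq(0, W - size, by = stride)
  out <- list()
  for (r in rows) {
    for (cc in cols) {
      out[[length(out) + 1L]] <- structure(list(
        srs_patch = srs[(r + 1):(r + size), (cc + 1):(cc + size), ,
                        drop = FALSE],
        he_patch = he[(r + 1):(r + size), (cc + 1):(cc + size), ,
                      drop = FALSE],
        origin = c(row = r, col = cc), source_id = source_id
      ), class = "patch_record")
    }
  }
  out
}

#' Reassemble patches by their origins
#'
#' Inverse of [tile_patches()] for non-overlapping grids: places each
#' patch's H&E (or SRS) member back at its origin.
#'
#' @param patches List of `patch_record`.
#' @param shape Output `c(H, W)`.
#' @param member `"he_patch"` or `"srs_patch"`.
#' @return Reassembled array.
#' @export
untile_patches <- function(patches, shape, member = "he_patch") {
  if (!length(patches)) stop("no patches to reassemble")
  C <- dim(patches[[1]][[member]])[3]
  out <- array(0, c(shape, C))
  for (p in patches) {
    sz <- dim(p[[member]])[1:2]
    out[(p$origin[1] + 1):(p$origin[1] + sz[1]),
        (p$origin[2] + 1):(p$origin[2] + sz[2]), ] <- p[[member]]
  }
  out
}

#' Seeded paired augmentation: random crop plus random affine
#'
#' Draws one crop offset uniformly over all in-bounds positions and applies
#' it to both patch members, then applies one random affine (rotation,
#' isotropic scale, shear) identically to both. With the default 500 -> 384
#' crop the offset is uniform on \{0..116\} per axis. Safe bounds for a
#' fill-free output: rotation and shear at 0 with scale at least 1; the
#' default mild ranges can pull a thin border of fill pixels into the
#' output, which matches how training augmentation treats patch edges.
#'
#' @param patch A `patch_record` (members at least `crop` in both dims).
#' @param crop Output side, pixels (default 384).
#' @param seed Integer seed shared by both members.
#' @param rotation_deg,scale_range,shear_deg Affine ranges; set
#'   `rotation_deg = 0, shear_deg = 0, scale_range = c(1, 1)` to disable.
#' @return Augmented `patch_record` with attribute `crop_offset`.
#' @export
augment_patch <- function(patch, crop = 384, seed = 1, rotation_deg = 10,
                          scale_range = c(0.9, 1.1), shear_deg = 5) {
  d <- dim(patch$srs_patch)
  if (d[1] < crop || d[2] < crop) stop("crop larger than patch")
  with_seed(seed, {
    off_r <- sample.int(d[1] - crop + 1L, 1L) - 1L
    off_c <- sample.int(d[2] - crop + 1L, 1L) - 1L
    theta <- runif(1, -rotation_deg, rotation_deg) * pi / 180
    sc <- runif(1, scale_range[1], scale_range[2])
    sh <- tan(runif(1, -shear_deg, shear_deg) * pi / 180)
    crop_one <- function(x) {
      x[(off_r + 1):(off_r + crop), (off_c + 1):(off_c + crop), ,
        drop = FALSE]
    }
    srs <- crop_one(patch$srs_patch)
    he <- crop_one(patch$he_patch)
    if (theta != 0 || sc != 1 || sh != 0) {
      ctr <- (crop - 1) / 2
      R <- sc * matrix(c(cos(theta), sin(theta),
                         -sin(theta), cos(theta)), 2, 2)
      S <- matrix(c(1, 0, sh, 1), 2, 2)
      L <- R %*% S
      shift <- c(ctr, ctr) - L %*% c(ctr, ctr)
      A <- structure(cbind(L, shift), class = "affine_transform")
      srs <- warp(srs, A)
      he <- warp(he, A)
    }
    structure(list(
      srs_patch = srs, he_patch = he, origin = patch$origin,
      source_id = patch$source_id
    ), class = "patch_record", crop_offset = c(row = off_r, col = off_c),
    affine = c(theta = theta, scale = sc, shear = sh))
  })
}

#' Two-colour SRS rendering
#'
#' The conventional dual-frequency false-colour view: blue is the
#' max-normalised nonnegative part of S2933 - S2847 (mimicking a DAPI-like
#' nuclear stain), green is max-normalised S2847 (cytoplasm/lipid), red is
#' identically zero.
#'
#' @param bands A [band_image()] containing 2847 and 2933 cm^-1 channels.
#' @return H x W x 3 array in \[0, 1\].
#' @export
two_color <- function(bands) {
  i47 <- band_channel(bands, 2847)
  i33 <- band_channel(bands, 2933)
  s47 <- as_bare_array(bands)[, , i47]
  s33 <- as_bare_array(bands)[, , i33]
  blue <- pmax(s33 - s47, 0)
  if (max(blue) > 0) blue <- blue / max(blue)
  green <- s47
  if (max(green) > 0) green <- green / max(green)
  out <- array(0, c(dim(s47), 3))
  out[, , 2] <- green
  out[, , 3] <- blue
  out
}
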