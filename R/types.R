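#' Tissue class codes used in label masks
#'
#' Integer codes for the pixel classes of a phantom label mask. Every pixel of
#' a mask carries exactly one of these codes, so class areas always partition
#' the image area.
#'
#' @format Named integer vector: `background = 0`, `stroma = 1`,
#'   `epithelium = 2`, `nucleus = 3`, `lumen = 4`, `lipid_droplet = 5`.
#' @export
MASK_CLASSES <- c(
  background = 0L, stroma = 1L, epithelium = 2L,
  nucleus = 3L, lumen = 4L, lipid_droplet = 5L
)

#' Construct the hyperspectral wavenumber axis
#'
#' Raman shifts of the high-wavenumber CH-stretching window used for
#' hyperspectral SRS acquisition: 2800 to 3105 cm^-1 sampled every 4 cm^-1
#' (77 bands). The axis must be strictly increasing and uniformly spaced.
#'
#' @param from,to Range covered, cm^-1. The last shift is the largest value
#'   of the form `from + k*by` not exceeding `to`.
#' @param by Spacing, cm^-1.
#' @return Numeric vector of Raman shifts (class `wavenumber_axis`).
#' @export
wavenumber_axis <- function(from = 2800, to = 3105, by = 4) {
  if (by <= 0 || to <= from) stop("invalid wavenumber axis range")
  shifts <- seq(from, to, by = by)
  structure(shifts, class = "wavenumber_axis")
}

assert_axis <- function(axis) {
  if (length(axis) < 2 || any(!is.finite(axis)) || any(diff(axis) <= 0)) {
    stop("wavenumber axis must be finite and strictly increasing")
  }
  invisible(axis)
}

#' Hyperspectral SRS cube
#'
#' Wraps an H x W x B array of nonnegative SRS intensities together with its
#' wavenumber axis and acquisition metadata.
#'
#' @param values H x W x B numeric array, arbitrary intensity units.
#' @param axis Wavenumber axis (length B), cm^-1.
#' @param pixel_size_um Spatial sampling, micrometres.
#' @param depth_um Depth of the optical section plane, micrometres.
#' @return An `srs_cube` object.
#' @export
srs_cube <- function(values, axis, pixel_size_um = 1, depth_um = 0) {
  assert_axis(axis)
  if (length(dim(values)) != 3L) stop("cube values must be H x W x B")
  if (dim(values)[3] != length(axis)) {
    stop("cube band count must equal the axis length")
  }
  if (any(!is.finite(values))) stop("cube values must be finite")
  structure(values,
    axis = as.numeric(axis), pixel_size_um = pixel_size_um,
    depth_um = depth_um, class = "srs_cube"
  )
}

#' @export
print.srs_cube <- function(x, ...) {
  d <- dim(x)
  ax <- attr(x, "axis")
  cat(sprintf(
    "<srs_cube> %d x %d px, %d bands (%g-%g cm^-1), pixel %g um, depth %g um\n",
    d[1], d[2], d[3], min(ax), max(ax), attr(x, "pixel_size_um"),
    attr(x, "depth_um")
  ))
  invisible(x)
}

#' Discrete-frequency band image
#'
#' An H x W x K array holding intensities at K named Raman shifts (the
#' discrete-frequency acquisition mode). Channel names record the requested
#' shifts in cm^-1.
#'
#' @param values H x W x K numeric array.
#' @param shifts Numeric vector of K Raman shifts, cm^-1.
#' @param pixel_size_um,depth_um Acquisition metadata.
#' @return A `band_image` object.
#' @export
band_image <- function(values, shifts, pixel_size_um = 1, depth_um = 0) {
  if (length(dim(values)) != 3L) stop("band image values must be H x W x K")
  if (dim(values)[3] != length(shifts)) {
    stop("band image channel count must equal the shift count")
  }
  structure(values,
    shifts = as.numeric(shifts), pixel_size_um = pixel_size_um,
    depth_um = depth_um, class = "band_image"
  )
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf(
    "<band_image> %d x %d px, channels: %s\n", dim(x)[1], dim(x)[2],
    paste(attr(x, "shifts"), collapse = ", ")
  ))
  invisible(x)
}

# Channel index of a named shift in a band image; errors if absent.
band_channel <- function(bands, shift) {
  shifts <- attr(bands, "shifts")
  i <- which(shifts == shift)
  if (length(i) != 1L) {
    stop(sprintf("band image has no %g cm^-1 channel (has: %s)",
                 shift, paste(shifts, collapse = ", ")))
  }
  i
}

#' Label mask
#'
#' H x W integer matrix of tissue class codes (see [MASK_CLASSES]).
#'
#' @param labels Integer matrix with values in `MASK_CLASSES`.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(MASK_CLASSES))
  if (length(bad)) stop("unknown class codes: ", paste(bad, collapse = ", "))
  structure(labels, class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = MASK_CLASSES,
                      labels = names(MASK_CLASSES)))
  cat(sprintf("<label_mask> %d x %d px\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

#' Count pixels per tissue class in a mask
#'
#' @param mask A [label_mask()].
#' @return Named integer vector over all classes (zero where absent).
#' @export
class_counts <- function(mask) {
  tab <- tabulate(as.vector(mask) + 1L, nbins = length(MASK_CLASSES))
  names(tab) <- names(MASK_CLASSES)
  tab
}

#' RGB stain-domain image
#'
#' H x W x 3 array with values in \[0, 1\]. `domain` records which staining
#' domain the image belongs to: measured fresh-frozen H&E (`FF_HE`), measured
#' FFPE H&E (`FFPE_HE`), or the model outputs (`VIRTUAL_FF`, `VIRTUAL_FFPE`).
#'
#' @param values H x W x 3 numeric array in \[0, 1\].
#' @param domain One of `"FF_HE"`, `"FFPE_HE"`, `"VIRTUAL_FF"`, `"VIRTUAL_FFPE"`.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(values, domain = c("FF_HE", "FFPE_HE", "VIRTUAL_FF",
                                         "VIRTUAL_FFPE")) {
  domain <- match.arg(domain)
  if (length(dim(values)) != 3L || dim(values)[3] != 3L) {
    stop("rgb image must be H x W x 3")
  }
  if (min(values) < 0 || max(values) > 1) {
    stop("rgb values must lie in [0, 1]")
  }
  structure(values, domain = domain, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, domain %s\n",
              dim(x)[1], dim(x)[2], attr(x, "domain")))
  invisible(x)
}

# Strip classes/attributes down to a bare numeric array.
as_bare_array <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}
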