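# Per-class spectral model for the tissue phantom.
#
# Each tissue class gets a CH-stretching-region spectrum built as a sum of
# Gaussian peaks over the wavenumber axis: the lipid CH2 symmetric stretch
# near 2847 cm^-1, the protein CH3 stretch near 2933 cm^-1, and smaller
# contributions near 2880, 2960, 2979 and 3062 cm^-1. Lipid droplets are
# dominated by the CH2 peak, so their 2847/2933 intensity ratio exceeds 1;
# the protein-rich classes (stroma, nuclei, epithelium) have the ratio below
# 1. That ordering is what the downstream ratio-threshold droplet statistic
# relies on.

# centre (cm^-1), width sigma (cm^-1), relative amplitude
.peak_tables <- list(
  lipid_droplet = cbind(
    c(2847, 2880, 2930, 3005),
    c(14, 20, 20, 25),
    c(1.00, 0.50, 0.30, 0.10)
  ),
  stroma = cbind(
    c(2933, 2880, 2847, 2979, 3062),
    c(22, 20, 15, 18, 18),
    c(1.00, 0.45, 0.40, 0.55, 0.22)
  ),
  nuclei = cbind(
    c(2933, 2847, 2960, 3062),
    c(22, 15, 18, 18),
    c(1.00, 0.30, 0.55, 0.18)
  ),
  epithelium = cbind(
    c(2933, 2847, 2880, 2979, 3062),
    c(22, 15, 20, 18, 18),
    c(1.00, 0.65, 0.50, 0.30, 0.15)
  )
)

.gauss_sum <- function(axis, peaks, baseline = 0.05) {
  s <- rep(baseline, length(axis))
  for (i in seq_len(nrow(peaks))) {
    s <- s + peaks[i, 3] * exp(-(axis - peaks[i, 1])^2 / (2 * peaks[i, 2]^2))
  }
  s
}

#' Build the per-class SRS spectral library
#'
#' Constructs max-normalised spectra for the four tissue classes (stroma,
#' nuclei, epithelium, lipid droplets) as sums of Gaussian peaks over the
#' given wavenumber axis, plus a small constant tissue baseline. The seed
#' applies a mild (within a few percent) reproducible jitter to peak
#' amplitudes and centres, emulating sample-to-sample spectral variation
#' without ever flipping the lipid-vs-protein band ordering.
#'
#' @param seed Integer seed for the amplitude/centre jitter.
#' @param axis Wavenumber axis, see [wavenumber_axis()].
#' @param jitter Relative amplitude jitter half-width (default 0.03); peak
#'   centres jitter by up to 2 cm^-1 at the default and scale with it.
#' @return A `spectral_library`: named list of numeric spectra (one per
#'   class, each with maximum exactly 1) with the axis attached.
#' @export
make_spectral_library <- function(seed = 1, axis = wavenumber_axis(),
                                  jitter = 0.03) {
  assert_axis(axis)
  spectra <- with_seed(seed, {
    lapply(.peak_tables, function(peaks) {
      p <- peaks
      p[, 3] <- p[, 3] * runif(nrow(p), 1 - jitter, 1 + jitter)
      # centre jitter scales with the amplitude jitter: +/- 2 cm^-1 at the
      # default jitter = 0.03
      p[, 1] <- p[, 1] + runif(nrow(p), -1, 1) * (2 * jitter / 0.03)
      s <- .gauss_sum(axis, p)
      s / max(s)
    })
  })
  names(spectra) <- names(.peak_tables)
  lib <- structure(spectra, axis = as.numeric(axis), seed = seed,
                   class = "spectral_library")
  stopifnot(
    spectral_ratio(lib, "lipid_droplet") > 1,
    spectral_ratio(lib, "stroma") < 1,
    spectral_ratio(lib, "nuclei") < 1,
    spectral_ratio(lib, "epithelium") < 1
  )
  lib
}

#' Band ratio of a library spectrum
#'
#' Evaluates I(num)/I(den) for one class of a spectral library, reading the
#' intensities at the axis entries nearest to the requested shifts. The
#' default 2847/2933 ratio is the lipid-droplet discriminant.
#'
#' @param library A `spectral_library`.
#' @param class Class name.
#' @param num,den Numerator and denominator Raman shifts, cm^-1.
#' @return Scalar intensity ratio.
#' @export
spectral_ratio <- function(library, class, num = 2847, den = 2933) {
  axis <- attr(library, "axis")
  s <- library[[class]]
  if (is.null(s)) stop("no such class in library: ", class)
  s[nearest_band(axis, num)] / s[nearest_band(axis, den)]
}

# Index of the axis entry nearest to `shift`; ties go to the lower shift
# (which.min returns the first minimum on an ascending axis).
nearest_band <- function(axis, shift) {
  if (shift < min(axis) || shift > max(axis)) {
    stop(sprintf("shift %g cm^-1 outside axis range [%g, %g]",
                 shift, min(axis), max(axis)))
  }
  which.min(abs(axis - shift))
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> classes: %s; %d bands; lipid 2847/2933 ratio %.2f\n",
    paste(names(x), collapse = ", "), length(attr(x, "axis")),
    spectral_ratio(x, "lipid_droplet")
  ))
  invisible(x)
}
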