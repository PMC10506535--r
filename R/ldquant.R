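# Lipid-droplet quantification from the 2847/2933 band ratio, per-ROI
# density, heterogeneity, and the group-comparison statistics.
#
# Droplets are CH2-dominated, so their SRS(2847)/SRS(2933) ratio exceeds 1
# while protein-rich tissue stays below 1; thresholding the ratio map
# segments droplets, and droplet density per region of interest is the
# droplet-pixel fraction of the ROI area. Group statistics follow the
# classical recipes (one-way ANOVA from explicit sums of squares,
# pooled-variance pairwise t tests, IQR/mean heterogeneity) so every number
# is reproducible by hand.

#' Region-of-interest annotation
#'
#' @param region Logical H x W matrix (TRUE inside the ROI) or a two-column
#'   matrix of polygon vertices (x, y in pixel coordinates) that is
#'   rasterised against `shape`.
#' @param class One of `"low"`, `"moderate"`, `"high"`, `"stroma"`.
#' @param shape Required when `region` is a polygon: `c(H, W)`.
#' @return An `roi_annotation` with a logical `mask` member.
#' @export
roi_annotation <- function(region, class = c("low", "moderate", "high",
                                             "stroma"), shape = NULL) {
  class <- match.arg(class)
  if (is.logical(region) && is.matrix(region)) {
    mask <- region
  } else {
    if (is.null(shape)) stop("polygon ROIs need the image shape")
    mask <- .rasterise_polygon(as.matrix(region), shape)
  }
  if (!any(mask)) stop("ROI region is empty")
  structure(list(mask = mask, class = class), class = "roi_annotation")
}

# Even-odd rule point-in-polygon rasterisation.
.rasterise_polygon <- function(verts, shape) {
  H <- shape[1]; W <- shape[2]
  xs <- verts[, 1]; ys <- verts[, 2]
  n <- length(xs)
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (ys[i] > py) != (ys[j] > py)
    xint <- xs[i] + (py - ys[i]) / (ys[j] - ys[i] + 1e-300) * (xs[j] - xs[i])
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  matrix(inside, H, W)
}

#' Lipid-droplet band-ratio map
#'
#' Elementwise r = S2847 / (S2933 + epsilon). Pixels whose denominator is at
#' or below `epsilon` are flagged invalid (attribute `valid`) and excluded
#' from downstream segmentation and densities.
#'
#' @param bands A [band_image()] with 2847 and 2933 cm^-1 channels.
#' @param epsilon Positive denominator guard (default 1e-6).
#' @return H x W ratio matrix with logical attribute `valid`.
#' @export
ratio_map <- function(bands, epsilon = 1e-6) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  s47 <- as_bare_array(bands)[, , band_channel(bands, 2847)]
  s33 <- as_bare_array(bands)[, , band_channel(bands, 2933)]
  r <- s47 / (s33 + epsilon)
  structure(r, valid = s33 > epsilon)
}

#' Default ratio threshold implied by a spectral library
#'
#' Midpoint of the library's lipid-droplet and epithelium 2847/2933 ratios:
#' the natural operating point separating the droplet class from the most
#' lipid-rich non-droplet tissue.
#'
#' @param library A `spectral_library`.
#' @return Scalar threshold.
#' @export
ld_default_threshold <- function(library) {
  (spectral_ratio(library, "lipid_droplet") +
     spectral_ratio(library, "epithelium")) / 2
}

#' Segment lipid droplets from a ratio map
#'
#' mask = (ratio > threshold), restricted to valid pixels, with connected
#' components (8-connectivity) smaller than `min_size` pixels removed.
#' Monotone in the threshold: a higher threshold always yields a subset.
#'
#' @param ratio Output of [ratio_map()].
#' @param threshold Positive ratio cut.
#' @param min_size Minimum component size in pixels (0 keeps everything).
#' @return Logical H x W droplet mask.
#' @export
segment_ld <- function(ratio, threshold, min_size = 0) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_size < 0) stop("min_size must be >= 0")
  valid <- attr(ratio, "valid")
  m <- unclass(ratio) > threshold
  if (!is.null(valid)) m <- m & valid
  if (min_size > 1 && any(m)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' Lipid-droplet density in a region of interest
#'
#' density = (droplet pixels inside the ROI) / (valid ROI pixels).
#'
#' @param mask Logical droplet mask from [segment_ld()].
#' @param roi An [roi_annotation()].
#' @param valid Optional logical matrix of valid pixels (from the ratio
#'   map); invalid pixels drop out of both numerator and denominator.
#' @return An `ld_result`: list with `roi`, `density`, `n_pixels`.
#' @export
ld_density <- function(mask, roi, valid = NULL) {
  r <- roi$mask
  if (!any(r)) stop("empty ROI")
  if (!is.null(valid)) r <- r & valid
  n <- sum(r)
  if (n == 0) stop("ROI contains no valid pixels")
  structure(list(roi = roi, density = sum(mask & r) / n, n_pixels = n),
            class = "ld_result")
}

#' Heterogeneity statistic: interquartile range over mean
#'
#' IQR uses linear-interpolation quantiles (R type 7); the denominator is
#' the arithmetic mean, which must be positive. Scale-invariant: scaling
#' all values by c > 0 leaves the statistic unchanged.
#'
#' @param values Nonempty numeric vector with positive mean.
#' @return Scalar IQR/mean.
#' @export
heterogeneity <- function(values) {
  if (!length(values)) stop("values must be nonempty")
  m <- mean(values)
  if (m <= 0) stop("heterogeneity undefined: mean must be positive")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / m
}

#' One-way analysis of variance from explicit sums of squares
#'
#' F = MS_between / MS_within with SSB and SSW accumulated directly; the
#' p value comes from the F distribution with (k - 1, N - k) degrees of
#' freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List `F`, `p`, `df_between`, `df_within`, `ss_between`,
#'   `ss_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  if (ssw == 0 && ssb == 0) stop("F undefined: no variance at all")
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, ss_between = ssb, ss_within = ssw)
}

#' Pairwise unpaired two-sample t tests
#'
#' Pooled-variance two-sided t test for every unordered pair of groups, no
#' multiplicity correction (raw pairwise tests). Welch's unpooled variant is
#' available behind `pooled = FALSE`.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance statistic (default) or Welch.
#' @return Data frame: `group1`, `group2`, `t`, `df`, `p`.
#' @export
pairwise_t <- function(groups, pooled = TRUE) {
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  combs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    a <- groups[[combs[1, j]]]; b <- groups[[combs[2, j]]]
    na <- length(a); nb <- length(b)
    dm <- mean(a) - mean(b)
    if (pooled) {
      sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(var(a) / na + var(b) / nb)
      df <- se^4 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
    }
    t <- if (se == 0) 0 else dm / se
    p <- if (se == 0) 1 else 2 * pt(-abs(t), df)
    data.frame(group1 = nms[combs[1, j]], group2 = nms[combs[2, j]],
               t = t, df = df, p = p)
  })
  do.call(rbind, rows)
}

#' Full lipid-droplet report over an annotated cohort
#'
#' Runs ratio map, segmentation and per-ROI density for every sample,
#' aggregates densities by class, and computes the group statistics:
#' one-way ANOVA, pairwise pooled t tests, and per-class IQR/mean
#' heterogeneity. Classes with fewer than 2 ROIs are excluded with a
#' warning.
#'
#' @param samples List of lists with members `bands` (a [band_image()]) and
#'   `roi` (an [roi_annotation()]).
#' @param threshold Ratio threshold; always recorded in the result.
#' @param min_size Minimum droplet component size, pixels.
#' @param epsilon Ratio-map denominator guard.
#' @return An `ld_group_stats`: per-class density lists, `anova`,
#'   `pairwise`, `heterogeneity`, `threshold`, `n` per class.
#' @export
ld_report <- function(samples, threshold, min_size = 0, epsilon = 1e-6) {
  densities <- list()
  for (s in samples) {
    r <- ratio_map(s$bands, epsilon)
    m <- segment_ld(r, threshold, min_size)
    d <- ld_density(m, s$roi, valid = attr(r, "valid"))
    cls <- s$roi$class
    densities[[cls]] <- c(densities[[cls]], d$density)
  }
  small <- names(densities)[vapply(densities, length, integer(1)) < 2]
  if (length(small)) {
    warning("classes excluded (fewer than 2 ROIs): ",
            paste(small, collapse = ", "))
    densities <- densities[!names(densities) %in% small]
  }
  if (length(densities) < 2) {
    stop("need at least 2 classes with >= 2 ROIs each")
  }
  het <- vapply(densities, function(v) {
    if (mean(v) > 0) heterogeneity(v) else NA_real_
  }, numeric(1))
  structure(list(
    densities = densities,
    n = vapply(densities, length, integer(1)),
    class_means = vapply(densities, mean, numeric(1)),
    anova = anova_oneway(densities),
    pairwise = pairwise_t(densities),
    heterogeneity = het,
    threshold = threshold, min_size = min_size
  ), class = "ld_group_stats")
}

#' @export
print.ld_group_stats <- function(x, ...) {
  cat(sprintf(
    "<ld_group_stats> %d classes, ANOVA F = %.2f (p = %.3g), threshold %.3f\n",
    length(x$densities), x$anova$F, x$anova$p, x$threshold
  ))
  means <- x$class_means
  for (nm in names(means)) {
    cat(sprintf("  %-9s n = %3d  mean density %.5f  IQR/mean %.3f\n",
                nm, x$n[[nm]], means[[nm]], x$heterogeneity[[nm]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ld_group_stats <- function(x, ...) {
  do.call(rbind, lapply(names(x$densities), function(nm) {
    data.frame(class = nm, density = x$densities[[nm]])
  }))
}

#' @exportS3Method generics::glance
glance.ld_group_stats <- function(x, ...) {
  data.frame(
    n_classes = length(x$densities), anova_F = x$anova$F,
    anova_p = x$anova$p, threshold = x$threshold
  )
}

#' Box plot of per-class droplet densities (log scale)
#'
#' @param object An `ld_group_stats`.
#' @param floor Densities below this are clamped for the log axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ld_group_stats <- function(object, floor = 1e-5, ...) {
  df <- tidy(object)
  df$density <- pmax(df$density, floor)
  df$class <- factor(df$class, levels = names(object$densities))
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = density)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "lipid-droplet density (log scale)") +
    ggplot2::theme_minimal()
}
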