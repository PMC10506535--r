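# Whole phantom samples, multi-depth stacks and on-disk datasets.

#' Generate one complete phantom sample
#'
#' Bundles a tissue mask with everything the rest of the pipeline consumes:
#' the hyperspectral cube, the 7-band discrete-frequency image, FF and FFPE
#' H&E renderings of the same mask, the clinical-concern class and the
#' achieved lipid-droplet area fraction. Regenerating with the same seed is
#' bit-identical.
#'
#' @param seed Integer seed.
#' @param shape `c(H, W)`.
#' @param grade_class `"low"`, `"moderate"` or `"high"`.
#' @param gland_count Number of glands.
#' @param ld_area_fraction Target droplet/epithelium pixel ratio.
#' @param noise_sd SRS noise level passed to [render_cube()].
#' @param library Spectral library (defaults to one built from `seed`).
#' @param artifacts FF [artifact_config()].
#' @param depth_um Depth metadata for the cube.
#' @param band_freqs Discrete shifts for the band image.
#' @return A `phantom_sample` list: `mask`, `cube`, `bands`, `ff_he`,
#'   `ffpe_he`, `grade_class`, `ld_area_fraction` (achieved), `seed`.
#' @export
generate_phantom_sample <- function(seed, shape = c(128, 128),
                                    grade_class = "low", gland_count = 4,
                                    ld_area_fraction = 0.02,
                                    noise_sd = 0.01, library = NULL,
                                    artifacts = artifact_config(),
                                    depth_um = 0,
                                    band_freqs = DEFAULT_BAND_SHIFTS) {
  if (is.null(library)) library <- make_spectral_library(seed)
  mask <- generate_tissue_mask(seed, shape, grade_class, gland_count,
                               ld_area_fraction)
  cube <- render_cube(mask, library, noise_sd = noise_sd, seed = seed,
                      depth_um = depth_um)
  bands <- sample_bands(cube, band_freqs)
  ff <- render_he(mask, "FF_HE", artifacts = artifacts, seed = seed)
  ffpe <- render_he(mask, "FFPE_HE", seed = seed)
  cc <- class_counts(mask)
  achieved <- if (cc[["epithelium"]] > 0) {
    cc[["lipid_droplet"]] / cc[["epithelium"]]
  } else 0
  structure(list(
    mask = mask, cube = cube, bands = bands, ff_he = ff, ffpe_he = ffpe,
    grade_class = grade_class, ld_area_fraction = achieved, seed = seed,
    library = library
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf(
    "<phantom_sample> %d x %d px, grade %s, LD fraction %.4f, seed %d\n",
    nrow(x$mask), ncol(x$mask), x$grade_class, x$ld_area_fraction, x$seed
  ))
  invisible(x)
}

# Morph gland parameters to a new depth: each gland drifts along its own
# direction and breathes in radius, both scaled by the decorrelation rate.
.morph_params <- function(params, dz, decorrelation) {
  params$glands <- lapply(params$glands, function(g) {
    g$cy <- g$cy + decorrelation * dz * g$drift[1]
    g$cx <- g$cx + decorrelation * dz * g$drift[2]
    g$r <- g$r * (1 + 0.3 * decorrelation * sin(g$angle0 + 0.05 * dz))
    g
  })
  params
}

#' Generate a multi-depth phantom stack
#'
#' One phantom sample per requested depth. Gland morphology evolves smoothly
#' with depth: each gland's centre drifts and its radius breathes at a rate
#' set by `decorrelation` (0 gives identical masks at all depths). With
#' `tumor_onset_um` set, additional fused high-grade glands are planted only
#' in planes at or beyond that depth, emulating a tumour that appears midway
#' through a thick section.
#'
#' @param seed Integer seed.
#' @param depths_um Nonempty nondecreasing depths, micrometres.
#' @param decorrelation Morphing rate per micrometre (dimensionless drift
#'   scale; default 0.15).
#' @param shape,grade_class,gland_count,ld_area_fraction,noise_sd As
#'   [generate_phantom_sample()].
#' @param tumor_onset_um Depth at which high-grade glands appear (`NULL` for
#'   none).
#' @param tumor_gland_count High-grade glands planted beyond the onset.
#' @return List of `phantom_sample`, one per depth, each with
#'   `meta$n_high_glands` recording how many high-grade glands its mask
#'   contains.
#' @export
generate_stack <- function(seed, depths_um, decorrelation = 0.15,
                           shape = c(128, 128), grade_class = "low",
                           gland_count = 4, ld_area_fraction = 0.02,
                           noise_sd = 0.01, tumor_onset_um = NULL,
                           tumor_gland_count = 2) {
  if (length(depths_um) == 0) stop("depths_um must be nonempty")
  if (is.unsorted(depths_um)) stop("depths_um must be nondecreasing")
  library <- make_spectral_library(seed)
  base <- gland_params(seed, shape, grade_class, gland_count)
  tumor <- if (!is.null(tumor_onset_um)) {
    tp <- gland_params(seed + 7L, shape, "high", tumor_gland_count)
    tp$glands
  } else list()
  lapply(depths_um, function(z) {
    params <- .morph_params(base, z - depths_um[1], decorrelation)
    n_high <- 0L
    if (length(tumor) && z >= tumor_onset_um) {
      params$glands <- c(params$glands, tumor)
      n_high <- length(tumor)
    }
    mask <- build_mask(params, nuclei_seed = seed + 1L)
    mask <- plant_droplets(mask, ld_area_fraction, seed = seed + 2L)
    cube <- render_cube(mask, library, noise_sd = noise_sd, seed = seed,
                        depth_um = z)
    bands <- sample_bands(cube)
    ff <- render_he(mask, "FF_HE", seed = seed)
    ffpe <- render_he(mask, "FFPE_HE", seed = seed)
    cc <- class_counts(mask)
    structure(list(
      mask = mask, cube = cube, bands = bands, ff_he = ff, ffpe_he = ffpe,
      grade_class = grade_class,
      ld_area_fraction = if (cc[["epithelium"]] > 0) {
        cc[["lipid_droplet"]] / cc[["epithelium"]]
      } else 0,
      seed = seed, library = library,
      meta = list(depth_um = z, n_high_glands = n_high,
                  decorrelation = decorrelation)
    ), class = "phantom_sample")
  })
}

#' Write a phantom dataset to disk
#'
#' Generates `n` phantom samples and writes each to its own subdirectory
#' (cube and band TIFFs with JSON sidecars, FF/FFPE PNGs, mask PNG) plus a
#' JSON manifest recording seeds, grade classes, achieved droplet fractions
#' and file paths. The dataset is fully reproducible from the manifest and
#' byte-identical across re-runs with the same configuration.
#'
#' @param n Number of samples (>= 1).
#' @param dir Output directory (created; must be writable).
#' @param seed Base seed; sample i uses `seed + i - 1`.
#' @param grade_mix Named counts over `low`/`moderate`/`high` summing to `n`
#'   (`NULL` = all `low`).
#' @param shape,gland_count,noise_sd Forwarded to
#'   [generate_phantom_sample()].
#' @param ld_fractions Named per-grade droplet fractions.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(n, dir, seed = 1, grade_mix = NULL,
                             shape = c(128, 128), gland_count = 4,
                             noise_sd = 0.01,
                             ld_fractions = c(low = 0.005, moderate = 0.05,
                                              high = 0.03)) {
  if (n < 1) stop("n must be >= 1")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  grades <- if (is.null(grade_mix)) {
    rep("low", n)
  } else {
    if (sum(grade_mix) != n) stop("grade_mix must sum to n")
    rep(names(grade_mix), times = grade_mix)
  }
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom_sample(
      seed = seed + i - 1L, shape = shape, grade_class = grades[i],
      gland_count = gland_count,
      ld_area_fraction = unname(ld_fractions[[grades[i]]]),
      noise_sd = noise_sd
    )
    sub <- file.path(dir, sprintf("sample_%03d", i))
    dir.create(sub, showWarnings = FALSE)
    write_cube(s$cube, file.path(sub, "cube.tif"))
    write_cube(s$bands, file.path(sub, "bands.tif"))
    write_rgb(s$ff_he, file.path(sub, "ff_he.png"))
    write_rgb(s$ffpe_he, file.path(sub, "ffpe_he.png"))
    write_mask(s$mask, file.path(sub, "mask.png"))
    entries[[i]] <- list(
      id = sprintf("sample_%03d", i), seed = seed + i - 1L,
      grade_class = grades[i], ld_area_fraction = s$ld_area_fraction,
      files = list(cube = "cube.tif", bands = "bands.tif",
                   ff_he = "ff_he.png", ffpe_he = "ffpe_he.png",
                   mask = "mask.png")
    )
  }
  manifest <- list(
    n = n, seed = seed, shape = shape, gland_count = gland_count,
    noise_sd = noise_sd, ld_fractions = as.list(ld_fractions),
    grade_counts = as.list(table(grades)), samples = entries
  )
  write_json_atomic(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Generate a phantom cohort for lipid-droplet statistics
#'
#' Builds a cohort of gland-level regions of interest across the four
#' statistical classes (stroma and low/moderate/high clinical concern) with
#' planted per-class droplet levels mirroring the qualitative ordering seen
#' in tissue: stroma carries essentially no droplets, moderate-concern
#' glands the most, high-concern glands intermediate, low-concern glands
#' little. Per-ROI planted fractions vary around the class mean so the
#' groups have within-class spread. Defaults to the full-scale design of 96
#' low / 56 moderate / 61 high gland patterns and 119 stromal ROIs when
#' `n_per_class` is `NULL`.
#'
#' @param n_per_class Single count used for every class, or `NULL` for the
#'   full-scale design.
#' @param seed Integer seed.
#' @param shape Per-sample image size.
#' @param class_means Named mean droplet area fractions (of ROI area).
#' @param noise_sd SRS noise level.
#' @return List with one element per ROI: `bands`, `roi` (an
#'   [roi_annotation()]), `class`, `planted_fraction` (achieved
#'   droplet/ROI-pixel ratio from the ground-truth mask).
#' @export
make_ld_cohort <- function(n_per_class = 20, seed = 1, shape = c(96, 96),
                           class_means = c(stroma = 0, low = 0.005,
                                           moderate = 0.05, high = 0.03),
                           noise_sd = 0) {
  counts <- if (is.null(n_per_class)) {
    c(stroma = 119, low = 96, moderate = 56, high = 61)
  } else {
    c(stroma = n_per_class, low = n_per_class, moderate = n_per_class,
      high = n_per_class)
  }
  library <- make_spectral_library(seed)
  out <- list()
  k <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      s <- seed + 1000L * match(cls, names(counts)) + i
      if (cls == "stroma") {
        mask <- generate_tissue_mask(s, shape, "low", gland_count = 0,
                                     ld_area_fraction = 0)
        roi_m <- unclass(mask) == MASK_CLASSES[["stroma"]]
      } else {
        f_target <- class_means[[cls]] *
          with_seed(s, runif(1, 0.7, 1.3))
        # convert ROI-area fraction to the epithelium-denominated request:
        # the ROI is the epithelial compartment (epithelium + droplets), so
        # request f/(1-f) droplets per remaining epithelium pixel, but
        # nuclei sit inside the ring and are excluded from the ROI
        mask <- generate_tissue_mask(s, shape, cls, gland_count = 3,
                                     ld_area_fraction =
                                       max(f_target, 1e-4) / (1 - min(f_target, 0.5)))
        roi_m <- unclass(mask) %in% MASK_CLASSES[c("epithelium",
                                                   "lipid_droplet")]
        dim(roi_m) <- dim(unclass(mask))
      }
      cube <- render_cube(mask, library, noise_sd = noise_sd, seed = s)
      bands <- sample_bands(cube)
      planted <- sum(unclass(mask) == MASK_CLASSES[["lipid_droplet"]] &
                       roi_m) / sum(roi_m)
      out[[k]] <- list(
        bands = bands, roi = roi_annotation(roi_m, cls), class = cls,
        planted_fraction = planted, mask = mask
      )
    }
  }
  attr(out, "library") <- library
  attr(out, "seed") <- seed
  out
}
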