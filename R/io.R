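# On-disk formats: multi-page TIFF + JSON sidecar for cubes and band
# images, 8-bit PNG for RGB renders and masks, JSON manifests and YAML run
# configuration. All writes are atomic (temp file + rename) so interrupted
# runs never leave half-written artifacts.

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path),
                  fileext = paste0(".", tools::file_ext(path), ".tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a hyperspectral cube or band image to disk
#'
#' Multi-page 32-bit TIFF (one page per band, ascending wavenumber order)
#' plus a JSON sidecar carrying `shifts_cm1`, `pixel_size_um`, `depth_um`
#' and the intensity `scale` the pages were divided by (TIFF pages live in
#' \[0, 1\]). Pages are stored at 32-bit sample depth, i.e. intensities are
#' quantised to one part in 2^32 of the scale -- finer than single-precision
#' float resolution. Values already on that grid (in particular anything
#' that has been through one write) round-trip through [read_cube()]
#' bit-identically.
#'
#' @param cube An [srs_cube()] or [band_image()].
#' @param path Output `.tif` path; the sidecar lands next to it.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  vals <- as_bare_array(cube)
  shifts <- attr(cube, "axis") %||% attr(cube, "shifts")
  scale <- max(vals, 1e-12)
  # quantise to the 32-bit sample grid ourselves (u of 0..2^32-1), and hand
  # the writer the sample centres so its truncation recovers u exactly
  G <- 2^32 - 1
  pages <- lapply(seq_len(dim(vals)[3]), function(b) {
    u <- round(vals[, , b] / scale * G)
    pmin((u + 0.5) / G, 1)
  })
  write_atomic(path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32L, reduce = FALSE)
  })
  write_json_atomic(list(
    shifts_cm1 = shifts,
    pixel_size_um = attr(cube, "pixel_size_um") %||% 1,
    depth_um = attr(cube, "depth_um") %||% 0,
    scale = scale,
    kind = if (inherits(cube, "srs_cube")) "cube" else "bands"
  ), .sidecar_path(path))
  invisible(path)
}

#' Read a hyperspectral cube or band image
#'
#' Inverse of [write_cube()]: validates that the TIFF page count matches the
#' sidecar's shift list and restores the intensity scale and metadata.
#'
#' @param path `.tif` path written by [write_cube()].
#' @return An [srs_cube()] or [band_image()], per the sidecar's `kind`.
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$shifts_cm1)) {
    stop(sprintf(
      "TIFF has %d pages but sidecar lists %d shifts",
      length(pages), length(meta$shifts_cm1)
    ))
  }
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  G <- 2^32 - 1
  for (b in seq_along(pages)) {
    u <- round(pages[[b]] * 2^32)  # the reader divides the raw sample by 2^32
    arr[, , b] <- u / G * meta$scale
  }
  if (identical(meta$kind, "cube")) {
    srs_cube(arr, meta$shifts_cm1, meta$pixel_size_um, meta$depth_um)
  } else {
    band_image(arr, meta$shifts_cm1, meta$pixel_size_um, meta$depth_um)
  }
}

#' Write / read an RGB image as 8-bit PNG
#'
#' @param img An [rgb_image()] (values in \[0, 1\]).
#' @param path PNG path.
#' @return `path` (write) / an [rgb_image()] (read; `domain` from the
#'   filename is not recoverable, defaults to `FF_HE`).
#' @export
write_rgb <- function(img, path) {
  write_atomic(path, function(tmp) png::writePNG(as_bare_array(img), tmp))
}

#' @rdname write_rgb
#' @param domain Domain tag to attach on read.
#' @export
read_rgb <- function(path, domain = "FF_HE") {
  rgb_image(png::readPNG(path), domain)
}

#' Write / read a label mask as single-page 8-bit PNG
#'
#' Class codes (see [MASK_CLASSES]) are stored directly as 8-bit grey
#' levels, so the file is readable by any image viewer and exactly
#' invertible.
#'
#' @param mask A [label_mask()].
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  write_atomic(path, function(tmp) {
    png::writePNG(unclass(mask) / 255, tmp)
  })
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  label_mask(matrix(as.integer(round(v * 255)), nrow(v), ncol(v)))
}

# Known run-config keys per section; unknown keys are rejected.
.config_schema <- list(
  global = c("seed", "out_dir", "desk_scale"),
  phantom = c("n_samples", "shape", "gland_count", "grade_mix",
              "ld_fractions", "noise_sd"),
  spectra = c("k", "holdout_fraction", "max_pixels"),
  train = c("phase1_iters", "phase2_iters", "iters", "batch", "lr0",
            "decay_factor", "decay_every", "alpha", "gamma", "lambda_cyc",
            "crop", "base_width", "depth"),
  ldquant = c("threshold", "min_size", "epsilon"),
  survey = c("ci_level")
)

#' Read and validate a run configuration
#'
#' YAML with sections `global`, `phantom`, `spectra`, `train`, `ldquant`,
#' `survey`; unknown sections or keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML path.
#' @return Validated nested list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_sections)) {
    stop("unknown config sections: ", paste(bad_sections, collapse = ", "))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown keys in [%s]: %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  structure(cfg, class = "run_config")
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg Config list.
#' @param dir Output directory.
#' @export
write_resolved_config <- function(cfg, dir) {
  write_atomic(file.path(dir, "resolved_config.yaml"), function(tmp) {
    yaml::write_yaml(unclass(cfg), tmp)
  })
}

#' Save / load a trained generator
#'
#' Checkpoint as RDS plus a JSON spec sidecar recording the architecture
#' and seeds for reproducibility.
#'
#' @param model An `srs_generator`.
#' @param path `.rds` path.
#' @export
save_generator <- function(model, path) {
  write_atomic(path, function(tmp) saveRDS(model, tmp))
  write_json_atomic(unclass(model$spec), .sidecar_path(path))
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "srs_generator")) stop("not a generator checkpoint")
  m
}
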