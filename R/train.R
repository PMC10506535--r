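# Training loops, learning-rate schedule, tiled inference and multi-depth
# virtual sectioning.
#
# The staining generator trains in two phases: a pixel-MSE phase that gets
# colours and layout right (but over-smooth), then a GAN phase continuing
# from those weights with adversarial + weighted MSE + perceptual terms and
# alternating 1:1 discriminator updates. The FF-to-FFPE translator trains as
# an unpaired cycle pair (G2 forward, G3 back) against per-domain
# multi-scale discriminators. Full-scale defaults mirror the published
# regime (50,000 + 200,000 iterations at batch 9; 100,000 at batch 6); the
# desk-scale presets train the same code on small phantoms in minutes.

#' Stepped exponential learning-rate schedule
#'
#' lr(t) = lr0 * factor^floor(t / every): the rate starts at `lr0` and is
#' multiplied by `factor` after every `every` iterations.
#'
#' @param lr0 Initial rate (> 0), default 1e-4.
#' @param factor Decay multiplier in (0, 1], default 0.96.
#' @param every Iterations between decays, default 1000.
#' @return Function mapping 0-based iteration to learning rate.
#' @export
lr_schedule <- function(lr0 = 1e-4, factor = 0.96, every = 1000) {
  if (lr0 <= 0 || factor <= 0 || factor > 1 || every < 1) {
    stop("invalid schedule parameters")
  }
  function(t) lr0 * factor^(t %/% every)
}

#' Staining-generator training configuration
#'
#' @param phase1_iters MSE-only iterations (default 50,000).
#' @param phase2_iters GAN iterations continuing from phase I (default
#'   200,000).
#' @param batch Batch size (default 9).
#' @param lr0,decay_factor,decay_every Learning-rate schedule, see
#'   [lr_schedule()].
#' @param weights A [loss_weights()].
#' @param crop Augmentation crop side (default 384 from 500 patches).
#' @param augment Apply the seeded crop+affine augmentation each iteration.
#' @param base_width,depth Generator size.
#' @param disc_layers Discriminator conv blocks.
#' @param seed Master seed for init, batching and augmentation.
#' @param desk_scale If `TRUE`, overrides to the small tested preset
#'   (300 + 300 iterations, batch 4, 64 px crop, width 16, no affine).
#' @return A `g1_config` list.
#' @export
g1_config <- function(phase1_iters = 50000, phase2_iters = 200000,
                      batch = 9, lr0 = 1e-4, decay_factor = 0.96,
                      decay_every = 1000, weights = loss_weights(),
                      crop = 384, augment = TRUE, base_width = 32,
                      depth = 3, disc_layers = 3, seed = 1,
                      desk_scale = FALSE) {
  cfg <- list(phase1_iters = phase1_iters, phase2_iters = phase2_iters,
              batch = batch, lr0 = lr0, decay_factor = decay_factor,
              decay_every = decay_every, weights = weights, crop = crop,
              augment = augment, base_width = base_width, depth = depth,
              disc_layers = disc_layers, seed = seed,
              desk_scale = desk_scale)
  if (desk_scale) {
    cfg$phase1_iters <- 300; cfg$phase2_iters <- 300; cfg$batch <- 4
    cfg$crop <- 64; cfg$base_width <- 16; cfg$depth <- 2
    cfg$augment <- FALSE
  }
  if (cfg$phase1_iters < 1 || cfg$phase2_iters < 0 || cfg$batch < 1) {
    stop("iteration and batch counts must be positive")
  }
  structure(cfg, class = "g1_config")
}

#' Cycle-translator training configuration
#'
#' @param iters Iterations (default 100,000).
#' @param batch Batch size (default 6).
#' @inheritParams g1_config
#' @return A `cycle_config` list.
#' @export
cycle_config <- function(iters = 100000, batch = 6, lr0 = 1e-4,
                         decay_factor = 0.96, decay_every = 1000,
                         weights = loss_weights(), base_width = 32,
                         depth = 3, disc_layers = 3, seed = 1,
                         desk_scale = FALSE) {
  cfg <- list(iters = iters, batch = batch, lr0 = lr0,
              decay_factor = decay_factor, decay_every = decay_every,
              weights = weights, base_width = base_width, depth = depth,
              disc_layers = disc_layers, seed = seed,
              desk_scale = desk_scale)
  if (desk_scale) {
    cfg$iters <- 400; cfg$batch <- 2; cfg$base_width <- 16; cfg$depth <- 2
  }
  if (cfg$iters < 1 || cfg$batch < 1) stop("counts must be positive")
  structure(cfg, class = "cycle_config")
}

.as_pair <- function(p) {
  if (!is.null(p$srs_patch)) list(x = p$srs_patch, y = p$he_patch)
  else if (!is.null(p$srs)) list(x = p$srs, y = p$he)
  else stop("patches must carry srs/he members")
}

.check_finite <- function(loss, t, what) {
  if (!is.finite(loss)) {
    stop(sprintf(
      "non-finite %s loss (%g) at iteration %d; lower the learning rate or inspect the data",
      what, loss, t
    ))
  }
}

#' Train the virtual-staining generator (two-phase)
#'
#' Phase I minimises the pixel MSE alone; phase II continues from the
#' phase-I weights with the full objective ([g1_total_loss()]) and
#' alternating (1:1) multi-scale-discriminator updates. Adam with the
#' stepped learning-rate schedule throughout; every iteration applies the
#' seeded paired augmentation when enabled. The returned history holds one
#' record per iteration and checksums of the weights at the phase boundary.
#'
#' @param patches Nonempty list of paired patches (`patch_record` or lists
#'   with `srs`/`he` members).
#' @param cfg A [g1_config()].
#' @return List: `generator`, `discriminators`, `history`
#'   (`training_history` data frame), `fx` (the perceptual extractor).
#' @export
train_g1 <- function(patches, cfg = g1_config(desk_scale = TRUE)) {
  if (!length(patches)) stop("empty training set")
  pair1 <- .as_pair(patches[[1]])
  in_ch <- dim(pair1$x)[3]
  gen <- build_generator(generator_spec(in_ch, 3, cfg$base_width, cfg$depth,
                                        seed = cfg$seed))
  disc <- build_discriminators(discriminator_spec(3, cfg$disc_layers,
                                                  cfg$base_width,
                                                  seed = cfg$seed + 1L))
  fx <- feature_extractor(3, "random_seeded", seed = cfg$seed + 2L)
  sched <- lr_schedule(cfg$lr0, cfg$decay_factor, cfg$decay_every)
  opt_g <- adam_init(gen$params)
  dparams <- c(stats::setNames(disc$d1, paste0("d1.", names(disc$d1))),
               stats::setNames(disc$d2, paste0("d2.", names(disc$d2))))
  opt_d <- adam_init(dparams)
  total_iters <- cfg$phase1_iters + cfg$phase2_iters
  hist <- data.frame(
    iteration = seq_len(total_iters), phase = NA_integer_, lr = NA_real_,
    loss_total = NA_real_, loss_mse = NA_real_, loss_adv = NA_real_,
    loss_perc = NA_real_, loss_d = NA_real_
  )
  w <- cfg$weights
  phase1_checksum <- NULL
  phase2_init_checksum <- NULL
  with_seed(cfg$seed + 10L, {
    for (t in seq_len(total_iters)) {
      phase <- if (t <= cfg$phase1_iters) 1L else 2L
      if (phase == 2L && is.null(phase2_init_checksum)) {
        phase2_init_checksum <- param_checksum(gen$params)
      }
      lr <- sched(t - 1L)
      idx <- sample.int(length(patches), cfg$batch, replace = TRUE)
      gacc <- NULL
      dacc <- NULL
      terms <- c(total = 0, mse = 0, adv = 0, perc = 0, d = 0)
      for (j in idx) {
        pr <- .as_pair(patches[[j]])
        if (cfg$augment) {
          aug <- augment_patch(
            structure(list(srs_patch = pr$x, he_patch = pr$y,
                           origin = c(0, 0), source_id = "train"),
                      class = "patch_record"),
            crop = cfg$crop,
            seed = sample.int(.Machine$integer.max, 1)
          )
          pr <- list(x = aug$srs_patch, y = aug$he_patch)
        }
        fwd <- generator_forward(gen, pr$x)
        fake <- fwd$y
        if (phase == 1L) {
          l <- loss_mse(fake, pr$y)
          terms["mse"] <- terms["mse"] + l
          terms["total"] <- terms["total"] + l
          bk <- generator_backward(gen, fwd$cache, grad_mse(fake, pr$y))
          gacc <- .acc(gacc, bk$grads)
        } else {
          md <- msd_forward(disc, fake)
          gl <- g1_total_loss(fake, pr$y, md$scores, fx, w)
          terms["mse"] <- terms["mse"] + gl$mse
          terms["adv"] <- terms["adv"] + gl$adversarial
          terms["perc"] <- terms["perc"] + gl$perceptual
          terms["total"] <- terms["total"] + gl$total
          dadv <- msd_backward(disc, md$cache,
                               grad_adversarial(md$scores, 1),
                               want_params = FALSE)$dx
          dfake <- dadv + w$alpha * grad_mse(fake, pr$y) +
            w$gamma * grad_perceptual(fake, pr$y, fx)
          bk <- generator_backward(gen, fwd$cache, dfake)
          gacc <- .acc(gacc, bk$grads)
          # discriminator step on real and (detached) fake; the fake pass
          # reuses the score cache computed for the generator update
          mr <- msd_forward(disc, pr$y)
          dl <- 0.5 * (loss_adversarial(mr$scores, 1) +
                         loss_adversarial(md$scores, 0))
          terms["d"] <- terms["d"] + dl
          br <- msd_backward(disc, mr$cache,
                             lapply(grad_adversarial(mr$scores, 1),
                                    function(g) 0.5 * g))
          bf <- msd_backward(disc, md$cache,
                             lapply(grad_adversarial(md$scores, 0),
                                    function(g) 0.5 * g))
          dg <- c(stats::setNames(Map(`+`, br$grads1, bf$grads1),
                                  paste0("d1.", names(br$grads1))),
                  stats::setNames(Map(`+`, br$grads2, bf$grads2),
                                  paste0("d2.", names(br$grads2))))
          dacc <- .acc(dacc, dg)
        }
      }
      nb <- length(idx)
      terms <- terms / nb
      .check_finite(terms[["total"]], t, "generator")
      gacc <- lapply(gacc, function(g) g / nb)
      st <- adam_step(gen$params, gacc, opt_g, lr)
      gen$params <- st$params; opt_g <- st$state
      if (phase == 2L) {
        .check_finite(terms[["d"]], t, "discriminator")
        dacc <- lapply(dacc, function(g) g / nb)
        st <- adam_step(dparams, dacc, opt_d, lr)
        dparams <- st$params; opt_d <- st$state
        disc$d1 <- stats::setNames(
          dparams[paste0("d1.", names(disc$d1))], names(disc$d1))
        disc$d2 <- stats::setNames(
          dparams[paste0("d2.", names(disc$d2))], names(disc$d2))
      }
      hist$phase[t] <- phase
      hist$lr[t] <- lr
      hist$loss_total[t] <- terms[["total"]]
      hist$loss_mse[t] <- terms[["mse"]]
      hist$loss_adv[t] <- if (phase == 2L) terms[["adv"]] else NA_real_
      hist$loss_perc[t] <- if (phase == 2L) terms[["perc"]] else NA_real_
      hist$loss_d[t] <- if (phase == 2L) terms[["d"]] else NA_real_
      if (t == cfg$phase1_iters) {
        phase1_checksum <- param_checksum(gen$params)
      }
    }
  })
  if (is.null(phase2_init_checksum)) {
    phase2_init_checksum <- param_checksum(gen$params)
  }
  history <- structure(hist, class = c("training_history", "data.frame"),
                       config = cfg,
                       phase1_final_checksum = phase1_checksum,
                       phase2_initial_checksum = phase2_init_checksum)
  list(generator = gen, discriminators = disc, history = history, fx = fx)
}

.acc <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  Map(`+`, acc, grads)
}

#' Reproducible unpaired batch-index stream
#'
#' The per-iteration sample indices drawn from the two unpaired pools during
#' cycle training. Exposed so the sampling can be audited: the streams are
#' reproducible under the seed and independent across pools.
#'
#' @param n_a,n_b Pool sizes.
#' @param iters Iterations.
#' @param batch Batch size.
#' @param seed Seed.
#' @return List of two `iters` x `batch` index matrices `a` and `b`.
#' @export
cycle_index_stream <- function(n_a, n_b, iters, batch, seed) {
  with_seed(seed, {
    a <- matrix(0L, iters, batch)
    b <- matrix(0L, iters, batch)
    for (t in seq_len(iters)) {
      a[t, ] <- sample.int(n_a, batch, replace = TRUE)
      b[t, ] <- sample.int(n_b, batch, replace = TRUE)
    }
    list(a = a, b = b)
  })
}

#' Train the unpaired FF-to-FFPE cycle translator
#'
#' Each iteration draws independent samples from the virtual-stain and FFPE
#' pools, updates the forward translator G2 (FF-style to FFPE-like) and the
#' backward translator G3 against their per-domain multi-scale
#' discriminators, with the lambda-weighted two-sided cycle loss tying the
#' pair together.
#'
#' @param vs_images Nonempty list of H x W x 3 arrays (virtual-stain / FF
#'   domain).
#' @param ffpe_images Nonempty list of H x W x 3 arrays (FFPE domain);
#'   unpaired with `vs_images`.
#' @param cfg A [cycle_config()].
#' @return List: `g2`, `g3`, `discriminators` (per domain), `history`.
#' @export
train_cycle <- function(vs_images, ffpe_images,
                        cfg = cycle_config(desk_scale = TRUE)) {
  if (!length(vs_images) || !length(ffpe_images)) {
    stop("both unpaired pools must be nonempty")
  }
  g2 <- build_generator(generator_spec(3, 3, cfg$base_width, cfg$depth,
                                       seed = cfg$seed))
  g3 <- build_generator(generator_spec(3, 3, cfg$base_width, cfg$depth,
                                       seed = cfg$seed + 1L))
  d_ffpe <- build_discriminators(discriminator_spec(3, cfg$disc_layers,
                                                    cfg$base_width,
                                                    seed = cfg$seed + 2L))
  d_vs <- build_discriminators(discriminator_spec(3, cfg$disc_layers,
                                                  cfg$base_width,
                                                  seed = cfg$seed + 3L))
  fxw <- cfg$weights
  sched <- lr_schedule(cfg$lr0, cfg$decay_factor, cfg$decay_every)
  idxs <- cycle_index_stream(length(vs_images), length(ffpe_images),
                             cfg$iters, cfg$batch, cfg$seed + 20L)
  opt_g2 <- adam_init(g2$params); opt_g3 <- adam_init(g3$params)
  dp_ffpe <- c(stats::setNames(d_ffpe$d1, paste0("d1.", names(d_ffpe$d1))),
               stats::setNames(d_ffpe$d2, paste0("d2.", names(d_ffpe$d2))))
  dp_vs <- c(stats::setNames(d_vs$d1, paste0("d1.", names(d_vs$d1))),
             stats::setNames(d_vs$d2, paste0("d2.", names(d_vs$d2))))
  opt_dffpe <- adam_init(dp_ffpe); opt_dvs <- adam_init(dp_vs)
  hist <- data.frame(
    iteration = seq_len(cfg$iters), lr = NA_real_, loss_total = NA_real_,
    adv_g2 = NA_real_, adv_g3 = NA_real_, cycle_vs = NA_real_,
    cycle_ffpe = NA_real_, loss_d_ffpe = NA_real_, loss_d_vs = NA_real_
  )
  disc_half <- function(scores, target) {
    lapply(grad_adversarial(scores, target), function(g) 0.5 * g)
  }
  upd_disc <- function(disc, dparams) {
    disc$d1 <- stats::setNames(dparams[paste0("d1.", names(disc$d1))],
                               names(disc$d1))
    disc$d2 <- stats::setNames(dparams[paste0("d2.", names(disc$d2))],
                               names(disc$d2))
    disc
  }
  for (t in seq_len(cfg$iters)) {
    lr <- sched(t - 1L)
    acc_g2 <- NULL; acc_g3 <- NULL
    acc_dffpe <- NULL; acc_dvs <- NULL
    terms <- c(adv_g2 = 0, adv_g3 = 0, cyc_vs = 0, cyc_ffpe = 0,
               d_ffpe = 0, d_vs = 0)
    for (j in seq_len(cfg$batch)) {
      vs <- as_bare_array(vs_images[[idxs$a[t, j]]])
      fp <- as_bare_array(ffpe_images[[idxs$b[t, j]]])
      f2 <- generator_forward(g2, vs)      # fake FFPE
      f3a <- generator_forward(g3, f2$y)   # cycle back to VS
      f3 <- generator_forward(g3, fp)      # fake VS
      f2b <- generator_forward(g2, f3$y)   # cycle back to FFPE
      m2 <- msd_forward(d_ffpe, f2$y)
      m3 <- msd_forward(d_vs, f3$y)
      adv2 <- loss_adversarial(m2$scores, 1)
      adv3 <- loss_adversarial(m3$scores, 1)
      cyc_vs <- loss_cycle(vs, f3a$y)
      cyc_fp <- loss_cycle(fp, f2b$y)
      terms <- terms + c(adv2, adv3, cyc_vs, cyc_fp, 0, 0)
      # --- generator gradients -------------------------------------------
      # path A: vs -> G2 -> (adv at D_ffpe) + G3 -> cycle
      b3a <- generator_backward(g3, f3a$cache,
                                fxw$lambda_cyc * grad_cycle(vs, f3a$y),
                                want_params = TRUE)
      dfake_ffpe <- b3a$dx +
        msd_backward(d_ffpe, m2$cache, grad_adversarial(m2$scores, 1),
                     want_params = FALSE)$dx
      b2 <- generator_backward(g2, f2$cache, dfake_ffpe, want_params = TRUE)
      # path B: ffpe -> G3 -> (adv at D_vs) + G2 -> cycle
      b2b <- generator_backward(g2, f2b$cache,
                                fxw$lambda_cyc * grad_cycle(fp, f2b$y),
                                want_params = TRUE)
      dfake_vs <- b2b$dx +
        msd_backward(d_vs, m3$cache, grad_adversarial(m3$scores, 1),
                     want_params = FALSE)$dx
      b3 <- generator_backward(g3, f3$cache, dfake_vs, want_params = TRUE)
      acc_g2 <- .acc(.acc(acc_g2, b2$grads), b2b$grads)
      acc_g3 <- .acc(.acc(acc_g3, b3$grads), b3a$grads)
      # --- discriminator gradients (fakes detached; score caches from
      # the generator step are reused) -------------------------------------
      mr2 <- msd_forward(d_ffpe, fp)
      terms["d_ffpe"] <- terms["d_ffpe"] +
        0.5 * (loss_adversarial(mr2$scores, 1) +
                 loss_adversarial(m2$scores, 0))
      br <- msd_backward(d_ffpe, mr2$cache, disc_half(mr2$scores, 1))
      bf <- msd_backward(d_ffpe, m2$cache, disc_half(m2$scores, 0))
      acc_dffpe <- .acc(acc_dffpe, c(
        stats::setNames(Map(`+`, br$grads1, bf$grads1),
                        paste0("d1.", names(br$grads1))),
        stats::setNames(Map(`+`, br$grads2, bf$grads2),
                        paste0("d2.", names(br$grads2)))
      ))
      mr3 <- msd_forward(d_vs, vs)
      terms["d_vs"] <- terms["d_vs"] +
        0.5 * (loss_adversarial(mr3$scores, 1) +
                 loss_adversarial(m3$scores, 0))
      br <- msd_backward(d_vs, mr3$cache, disc_half(mr3$scores, 1))
      bf <- msd_backward(d_vs, m3$cache, disc_half(m3$scores, 0))
      acc_dvs <- .acc(acc_dvs, c(
        stats::setNames(Map(`+`, br$grads1, bf$grads1),
                        paste0("d1.", names(br$grads1))),
        stats::setNames(Map(`+`, br$grads2, bf$grads2),
                        paste0("d2.", names(br$grads2)))
      ))
    }
    nb <- cfg$batch
    terms <- terms / nb
    tot <- cycle_total_loss(c(terms[["adv_g2"]], terms[["adv_g3"]]),
                            c(terms[["cyc_vs"]], terms[["cyc_ffpe"]]), fxw)
    .check_finite(tot$total, t, "cycle")
    st <- adam_step(g2$params, lapply(acc_g2, function(g) g / nb), opt_g2, lr)
    g2$params <- st$params; opt_g2 <- st$state
    st <- adam_step(g3$params, lapply(acc_g3, function(g) g / nb), opt_g3, lr)
    g3$params <- st$params; opt_g3 <- st$state
    st <- adam_step(dp_ffpe, lapply(acc_dffpe, function(g) g / nb),
                    opt_dffpe, lr)
    dp_ffpe <- st$params; opt_dffpe <- st$state
    d_ffpe <- upd_disc(d_ffpe, dp_ffpe)
    st <- adam_step(dp_vs, lapply(acc_dvs, function(g) g / nb), opt_dvs, lr)
    dp_vs <- st$params; opt_dvs <- st$state
    d_vs <- upd_disc(d_vs, dp_vs)
    hist$lr[t] <- lr
    hist$loss_total[t] <- tot$total
    hist$adv_g2[t] <- terms[["adv_g2"]]; hist$adv_g3[t] <- terms[["adv_g3"]]
    hist$cycle_vs[t] <- terms[["cyc_vs"]]
    hist$cycle_ffpe[t] <- terms[["cyc_ffpe"]]
    hist$loss_d_ffpe[t] <- terms[["d_ffpe"]]
    hist$loss_d_vs[t] <- terms[["d_vs"]]
  }
  history <- structure(hist, class = c("training_history", "data.frame"),
                       config = cfg, lambda_cyc = fxw$lambda_cyc)
  list(g2 = g2, g3 = g3,
       discriminators = list(ffpe = d_ffpe, vs = d_vs), history = history)
}

# Pad an image (edge replication) to a multiple of 2^depth, run the
# generator, crop back.
predict_padded <- function(gen, x) {
  x <- as_bare_array(x)
  d <- dim(x)
  q <- 2^gen$spec$depth
  Hp <- ceiling(d[1] / q) * q
  Wp <- ceiling(d[2] / q) * q
  if (Hp == d[1] && Wp == d[2]) return(generator_forward(gen, x)$y)
  ridx <- c(seq_len(d[1]), rep(d[1], Hp - d[1]))
  cidx <- c(seq_len(d[2]), rep(d[2], Wp - d[2]))
  xp <- x[ridx, cidx, , drop = FALSE]
  y <- generator_forward(gen, xp)$y
  y[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

# Tile origins covering [0, extent - tile] with the last origin clamped so
# coverage is complete.
.tile_origins <- function(extent, tile, stride) {
  if (tile >= extent) return(0L)
  o <- seq(0L, extent - tile, by = stride)
  if (tail(o, 1) != extent - tile) o <- c(o, extent - tile)
  o
}

# Per-tile blend window: flat 1 in the interior, linear ramp across the
# overlap margin. Accumulated and normalised, the per-pixel weights of all
# covering tiles sum to exactly 1.
.blend_window <- function(tile, overlap) {
  ramp <- pmin(1, (seq_len(tile)) / (overlap + 1),
               (tile + 1 - seq_len(tile)) / (overlap + 1))
  outer(ramp, ramp)
}

#' Per-tile normalised blend weights
#'
#' Constructs the tiling grid of [infer_tiled()] and the per-tile weight
#' maps after normalisation by the accumulated per-pixel weight, so that at
#' every pixel the weights of all covering tiles sum to 1.
#'
#' @param shape `c(H, W)`.
#' @param tile Tile side.
#' @param overlap Overlap between adjacent tiles (0 <= overlap < tile).
#' @return List: `origins` (n x 2, 0-based), `weights` (list of tile x tile
#'   matrices, normalised in place on the accumulated field).
#' @export
tile_blend_weights <- function(shape, tile, overlap = 0) {
  if (overlap < 0 || overlap >= tile) stop("need 0 <= overlap < tile")
  stride <- tile - overlap
  oy <- .tile_origins(shape[1], tile, stride)
  ox <- .tile_origins(shape[2], tile, stride)
  origins <- cbind(row = rep(oy, times = length(ox)),
                   col = rep(ox, each = length(oy)))
  win <- .blend_window(tile, overlap)
  ty <- min(tile, shape[1]); tx <- min(tile, shape[2])
  total <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1]; cc <- origins[i, 2]
    total[(r + 1):(r + ty), (cc + 1):(cc + tx)] <-
      total[(r + 1):(r + ty), (cc + 1):(cc + tx)] + win[1:ty, 1:tx]
  }
  weights <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; cc <- origins[i, 2]
    win[1:ty, 1:tx] / total[(r + 1):(r + ty), (cc + 1):(cc + tx)]
  })
  list(origins = origins, weights = weights)
}

#' Tiled whole-image inference
#'
#' Processes overlapping tiles independently through the generator and
#' blends the outputs with weights that sum to 1 at every pixel, so output
#' dimensions equal input dimensions. With `tile` at least the image size
#' this is identical to direct single-pass inference.
#'
#' @param generator An `srs_generator`, or any function mapping an
#'   H x W x C array to an H x W x C' array (applied per tile).
#' @param image H x W x C input array.
#' @param tile Tile side; must be at least `2^depth` and divisible by it.
#' @param overlap Overlap between adjacent tiles, pixels.
#' @return H x W x `out_channels` array.
#' @export
infer_tiled <- function(generator, image, tile = 256, overlap = 32) {
  x <- as_bare_array(image)
  d <- dim(x)
  apply_gen <- if (is.function(generator)) {
    generator
  } else {
    function(p) predict_padded(generator, p)
  }
  q <- if (is.function(generator)) 1L else 2^generator$spec$depth
  if (tile < q) {
    stop(sprintf("tile smaller than the generator minimum size (%d)", q))
  }
  if (tile %% q != 0) stop(sprintf("tile must be divisible by %d", q))
  if (tile >= d[1] && tile >= d[2]) return(apply_gen(x))
  bw <- tile_blend_weights(d[1:2], tile, overlap)
  ty <- min(tile, d[1]); tx <- min(tile, d[2])
  out <- NULL
  for (i in seq_len(nrow(bw$origins))) {
    r <- bw$origins[i, 1]; cc <- bw$origins[i, 2]
    patch <- x[(r + 1):(r + ty), (cc + 1):(cc + tx), , drop = FALSE]
    yp <- apply_gen(patch)
    if (is.null(out)) out <- array(0, c(d[1], d[2], dim(yp)[3]))
    wmat <- bw$weights[[i]]
    for (k in seq_len(dim(yp)[3])) {
      out[(r + 1):(r + ty), (cc + 1):(cc + tx), k] <-
        out[(r + 1):(r + ty), (cc + 1):(cc + tx), k] + yp[, , k] * wmat
    }
  }
  out
}

#' Multi-depth virtual sectioning
#'
#' Applies the staining generator and then the FFPE translator to each
#' depth plane of a band-image stack independently, producing paired
#' virtual-FF and virtual-FFPE images per depth with the depth metadata
#' propagated.
#'
#' @param g1 Trained staining generator (band-image input).
#' @param g2 Trained FF-to-FFPE translator (RGB input).
#' @param stack List of [band_image()] at different depths.
#' @param tile,overlap Passed to [infer_tiled()].
#' @return List per plane: `virtual_ff`, `virtual_ffpe` ([rgb_image()]s),
#'   `depth_um`.
#' @export
virtual_sectioning <- function(g1, g2, stack, tile = 256, overlap = 32) {
  lapply(stack, function(bands) {
    vf <- infer_tiled(g1, bands, tile, overlap)
    vffpe <- infer_tiled(g2, vf, tile, overlap)
    list(
      virtual_ff = rgb_image(clamp01(vf), "VIRTUAL_FF"),
      virtual_ffpe = rgb_image(clamp01(vffpe), "VIRTUAL_FFPE"),
      depth_um = attr(bands, "depth_um")
    )
  })
}

#' @export
print.training_history <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<training_history> %d iterations, final total loss %.4g\n",
              nrow(x), tail(x$loss_total, 1)))
  invisible(x)
}

#' Loss curves of a training run
#'
#' @param object A `training_history`.
#' @param ... Unused.
#' @return A ggplot object with one line per recorded loss term.
#' @exportS3Method ggplot2::autoplot
autoplot.training_history <- function(object, ...) {
  df <- as.data.frame(object)
  terms <- setdiff(names(df), c("iteration", "phase", "lr"))
  long <- do.call(rbind, lapply(terms, function(nm) {
    data.frame(iteration = df$iteration, term = nm, value = df[[nm]])
  }))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value,
                                     colour = term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
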