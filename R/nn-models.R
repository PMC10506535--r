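# Generator and discriminator architectures.
#
# The generator is a compact U-Net: per level a 3x3 conv + instance norm +
# leaky ReLU whose output is kept as the skip, a stride-2 conv to descend,
# a bottleneck conv, and per decoder level nearest-neighbour upsampling,
# conv, skip concatenation and a mixing conv; a final 1x1 conv + sigmoid
# maps to [0,1] per channel. Discriminators are PatchGAN-style stacks of
# stride-2 convs emitting a spatial score map; the multi-scale pair applies
# the identical architecture to the full-resolution input and to its 2x
# average-pooled version.

#' Generator specification
#'
#' @param in_channels Input channels (7 for the SRS-to-H&E stainer, 3 for
#'   the FF-to-FFPE translators).
#' @param out_channels Output channels (3 for RGB).
#' @param base_width Channel count at the first level.
#' @param depth Number of down/up levels (>= 1); inputs must be divisible
#'   by `2^depth`.
#' @param seed Weight-initialisation seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(in_channels = 7, out_channels = 3,
                           base_width = 16, depth = 2, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 base_width = base_width, depth = depth, seed = seed),
            class = "generator_spec")
}

#' Build a U-Net generator
#'
#' Encoder-decoder with a skip connection at every level and a final
#' sigmoid, so outputs always lie in \[0, 1\]. Parameters are seeded random
#' (He-style); identical spec and seed give identical initial weights.
#'
#' @param spec A [generator_spec()].
#' @return An `srs_generator` with elements `spec` and `params`.
#' @export
build_generator <- function(spec) {
  widths <- spec$base_width * 2^(seq_len(spec$depth) - 1)
  wb <- spec$base_width * 2^spec$depth
  params <- with_seed(spec$seed, {
    p <- list()
    cin <- spec$in_channels
    for (i in seq_len(spec$depth)) {
      k <- init_conv(3, 3, cin, widths[i])
      p[[paste0("enc", i, "_w")]] <- k$w; p[[paste0("enc", i, "_b")]] <- k$b
      k <- init_conv(3, 3, widths[i], widths[i])
      p[[paste0("down", i, "_w")]] <- k$w; p[[paste0("down", i, "_b")]] <- k$b
      cin <- widths[i]
    }
    k <- init_conv(3, 3, widths[spec$depth], wb)
    p$bott_w <- k$w; p$bott_b <- k$b
    ch <- wb
    for (i in rev(seq_len(spec$depth))) {
      k <- init_conv(3, 3, ch, widths[i])
      p[[paste0("up", i, "_w")]] <- k$w; p[[paste0("up", i, "_b")]] <- k$b
      k <- init_conv(3, 3, 2 * widths[i], widths[i])
      p[[paste0("mix", i, "_w")]] <- k$w; p[[paste0("mix", i, "_b")]] <- k$b
      ch <- widths[i]
    }
    k <- init_conv(1, 1, widths[1], spec$out_channels, gain = 1)
    p$fin_w <- k$w; p$fin_b <- k$b
    p
  })
  structure(list(spec = spec, params = params), class = "srs_generator")
}

#' @export
print.srs_generator <- function(x, ...) {
  cat(sprintf(
    "<srs_generator> %d -> %d channels, depth %d, base width %d, %d parameters\n",
    x$spec$in_channels, x$spec$out_channels, x$spec$depth,
    x$spec$base_width, n_params(x$params)
  ))
  invisible(x)
}

#' Total parameter count of a model
#' @param params Parameter list (or a model with a `params` element).
#' @return Integer count.
#' @export
n_params <- function(params) {
  if (!is.null(params$params)) params <- params$params
  sum(vapply(params, length, integer(1)))
}

.check_divisible <- function(d, depth) {
  q <- 2^depth
  if (d[1] %% q != 0 || d[2] %% q != 0) {
    stop(sprintf(
      "input %d x %d not divisible by 2^depth = %d; pad to %d x %d",
      d[1], d[2], q, ceiling(d[1] / q) * q, ceiling(d[2] / q) * q
    ))
  }
}

# Full generator forward pass; returns output and the cache stack needed by
# generator_backward.
generator_forward <- function(gen, x) {
  spec <- gen$spec; p <- gen$params
  d <- dim(x)
  if (d[3] != spec$in_channels) stop("input channel mismatch")
  .check_divisible(d, spec$depth)
  cache <- list()
  cur <- x
  for (i in seq_len(spec$depth)) {
    ce <- op_conv(cur, p[[paste0("enc", i, "_w")]], p[[paste0("enc", i, "_b")]])
    cn <- op_instnorm(ce$y)
    ca <- op_lrelu(cn$y)
    skip <- ca$y
    cd <- op_conv(skip, p[[paste0("down", i, "_w")]],
                  p[[paste0("down", i, "_b")]], stride = 2L)
    cda <- op_lrelu(cd$y)
    cache[[paste0("lvl", i)]] <- list(ce = ce$cache, cn = cn$cache,
                                      ca = ca$cache, cd = cd$cache,
                                      cda = cda$cache)
    cur <- cda$y
    cache[[paste0("skip", i)]] <- skip
  }
  cb <- op_conv(cur, p$bott_w, p$bott_b)
  cbn <- op_instnorm(cb$y)
  cba <- op_lrelu(cbn$y)
  cache$bott <- list(cb = cb$cache, cbn = cbn$cache, cba = cba$cache)
  cur <- cba$y
  for (i in rev(seq_len(spec$depth))) {
    cu <- op_upnearest2(cur)
    cc <- op_conv(cu$y, p[[paste0("up", i, "_w")]], p[[paste0("up", i, "_b")]])
    cca <- op_lrelu(cc$y)
    cat_ <- op_concat(cca$y, cache[[paste0("skip", i)]])
    cm <- op_conv(cat_$y, p[[paste0("mix", i, "_w")]],
                  p[[paste0("mix", i, "_b")]])
    cmn <- op_instnorm(cm$y)
    cma <- op_lrelu(cmn$y)
    cache[[paste0("dec", i)]] <- list(cu = cu$cache, cc = cc$cache,
                                      cca = cca$cache, cat = cat_$cache,
                                      cm = cm$cache, cmn = cmn$cache,
                                      cma = cma$cache)
    cur <- cma$y
  }
  cf <- op_conv(cur, p$fin_w, p$fin_b, stride = 1L, pad = 0L)
  cs <- op_sigmoid(cf$y)
  cache$fin <- list(cf = cf$cache, cs = cs$cache)
  list(y = cs$y, cache = cache)
}

# Backward pass through the generator. Returns the input gradient and, when
# want_params, the parameter gradients (named like the parameters).
generator_backward <- function(gen, cache, dy, want_params = TRUE) {
  spec <- gen$spec
  grads <- list()
  dcur <- bwd_sigmoid(cache$fin$cs, dy)
  gf <- bwd_conv(cache$fin$cf, dcur)
  if (want_params) { grads$fin_w <- gf$dw; grads$fin_b <- gf$db }
  dcur <- gf$dx
  dskip <- list()
  for (i in seq_len(spec$depth)) {
    cd <- cache[[paste0("dec", i)]]
    dma <- bwd_lrelu(cd$cma, dcur)
    dmn <- bwd_instnorm(cd$cmn, dma)
    gm <- bwd_conv(cd$cm, dmn)
    if (want_params) {
      grads[[paste0("mix", i, "_w")]] <- gm$dw
      grads[[paste0("mix", i, "_b")]] <- gm$db
    }
    parts <- bwd_concat(cd$cat, gm$dx)
    dskip[[i]] <- parts$db
    dca <- bwd_lrelu(cd$cca, parts$da)
    gc_ <- bwd_conv(cd$cc, dca)
    if (want_params) {
      grads[[paste0("up", i, "_w")]] <- gc_$dw
      grads[[paste0("up", i, "_b")]] <- gc_$db
    }
    dcur <- bwd_upnearest2(cd$cu, gc_$dx)
  }
  db <- cache$bott
  dba <- bwd_lrelu(db$cba, dcur)
  dbn <- bwd_instnorm(db$cbn, dba)
  gb <- bwd_conv(db$cb, dbn)
  if (want_params) { grads$bott_w <- gb$dw; grads$bott_b <- gb$db }
  dcur <- gb$dx
  for (i in rev(seq_len(spec$depth))) {
    cl <- cache[[paste0("lvl", i)]]
    dda <- bwd_lrelu(cl$cda, dcur)
    gd <- bwd_conv(cl$cd, dda)
    if (want_params) {
      grads[[paste0("down", i, "_w")]] <- gd$dw
      grads[[paste0("down", i, "_b")]] <- gd$db
    }
    dskip_total <- gd$dx + dskip[[i]]
    da <- bwd_lrelu(cl$ca, dskip_total)
    dn <- bwd_instnorm(cl$cn, da)
    ge <- bwd_conv(cl$ce, dn)
    if (want_params) {
      grads[[paste0("enc", i, "_w")]] <- ge$dw
      grads[[paste0("enc", i, "_b")]] <- ge$db
    }
    dcur <- ge$dx
  }
  list(dx = dcur, grads = grads)
}

#' Apply a generator to an image
#'
#' Forward pass only. The input must be divisible by `2^depth` in both
#' spatial dimensions (use [infer_tiled()] for arbitrary sizes).
#'
#' @param object An `srs_generator`.
#' @param x H x W x C array with `C = in_channels`.
#' @param ... Unused.
#' @return H x W x `out_channels` array in \[0, 1\].
#' @export
predict.srs_generator <- function(object, x, ...) {
  generator_forward(object, as_bare_array(x))$y
}

#' Discriminator specification
#'
#' @param in_channels Input channels scored.
#' @param layers Stride-2 conv-block count before the scoring conv.
#' @param base_width First-block channel count.
#' @param seed Weight-initialisation seed; both scales initialise from the
#'   same seed and therefore start identical.
#' @return A `discriminator_spec` (scales fixed at 2).
#' @export
discriminator_spec <- function(in_channels = 3, layers = 3, base_width = 16,
                               seed = 1) {
  structure(list(in_channels = in_channels, layers = layers,
                 base_width = base_width, scales = 2L, seed = seed),
            class = "discriminator_spec")
}

.disc_init <- function(spec) {
  with_seed(spec$seed, {
    p <- list()
    cin <- spec$in_channels
    w <- spec$base_width
    for (i in seq_len(spec$layers)) {
      k <- init_conv(3, 3, cin, w)
      p[[paste0("c", i, "_w")]] <- k$w; p[[paste0("c", i, "_b")]] <- k$b
      cin <- w
      w <- w * 2
    }
    k <- init_conv(3, 3, cin, 1, gain = 1)
    p$score_w <- k$w; p$score_b <- k$b
    p
  })
}

#' Build the multi-scale discriminator pair
#'
#' Two patch discriminators with identical layouts (and, from the shared
#' seed, identical initial weights): one scores the full-resolution image,
#' the other always scores the 2x average-pooled image.
#'
#' @param spec A [discriminator_spec()].
#' @return An `srs_discriminators` with per-scale parameter sets `d1`, `d2`.
#' @export
build_discriminators <- function(spec) {
  structure(list(spec = spec, d1 = .disc_init(spec), d2 = .disc_init(spec)),
            class = "srs_discriminators")
}

# Single-scale discriminator forward (with cache).
disc_forward <- function(spec, params, x) {
  if (min(dim(x)[1:2]) < 2^(spec$layers + 1)) {
    stop(sprintf("input smaller than discriminator receptive field (%d px)",
                 2^(spec$layers + 1)))
  }
  cache <- list()
  cur <- x
  for (i in seq_len(spec$layers)) {
    cc <- op_conv(cur, params[[paste0("c", i, "_w")]],
                  params[[paste0("c", i, "_b")]], stride = 2L)
    ca <- op_lrelu(cc$y)
    cache[[i]] <- list(cc = cc$cache, ca = ca$cache)
    cur <- ca$y
  }
  cs <- op_conv(cur, params$score_w, params$score_b)
  cache$score <- cs$cache
  list(y = cs$y, cache = cache)
}

disc_backward <- function(spec, cache, dy, want_params = TRUE) {
  grads <- list()
  g <- bwd_conv(cache$score, dy)
  if (want_params) { grads$score_w <- g$dw; grads$score_b <- g$db }
  dcur <- g$dx
  for (i in rev(seq_len(spec$layers))) {
    da <- bwd_lrelu(cache[[i]]$ca, dcur)
    gc_ <- bwd_conv(cache[[i]]$cc, da)
    if (want_params) {
      grads[[paste0("c", i, "_w")]] <- gc_$dw
      grads[[paste0("c", i, "_b")]] <- gc_$db
    }
    dcur <- gc_$dx
  }
  list(dx = dcur, grads = grads)
}

#' Score an image with the multi-scale discriminators
#'
#' @param disc An `srs_discriminators`.
#' @param x H x W x C array.
#' @return List of two spatial score maps: full resolution and 2x
#'   downsampled (the second has about half the spatial extent).
#' @export
discriminators_score <- function(disc, x) {
  s1 <- disc_forward(disc$spec, disc$d1, x)
  pool <- op_avgpool2(x)
  s2 <- disc_forward(disc$spec, disc$d2, pool$y)
  list(s1$y, s2$y)
}

# Forward with caches, for training.
msd_forward <- function(disc, x) {
  pool <- op_avgpool2(x)
  f1 <- disc_forward(disc$spec, disc$d1, x)
  f2 <- disc_forward(disc$spec, disc$d2, pool$y)
  list(scores = list(f1$y, f2$y),
       cache = list(f1 = f1$cache, f2 = f2$cache, pool = pool$cache))
}

# Backward through both scales given per-scale score gradients; returns the
# input gradient and (optionally) parameter gradients per scale.
msd_backward <- function(disc, cache, dscores, want_params = TRUE) {
  b1 <- disc_backward(disc$spec, cache$f1, dscores[[1]], want_params)
  b2 <- disc_backward(disc$spec, cache$f2, dscores[[2]], want_params)
  dx <- b1$dx + bwd_avgpool2(cache$pool, b2$dx)
  list(dx = dx, grads1 = b1$grads, grads2 = b2$grads)
}

#' Fixed perceptual feature extractor
#'
#' A small, never-trained stack of convolutional feature maps with named
#' taps, playing the role a pretrained deep feature network plays in
#' perceptual losses. Two provenances: `"random_seeded"` (default; a seeded
#' random two-layer conv stack, fully self-contained) and `"identity"` (a
#' single 1x1 identity convolution, under which the perceptual loss reduces
#' exactly to the pixel MSE — useful for verification). A pretrained deep
#' extractor can be supplied through the same interface by replacing the
#' weights, but none ships with the package.
#'
#' @param in_channels Image channels.
#' @param provenance `"random_seeded"` or `"identity"`.
#' @param seed Seed for the random stack.
#' @return A `feature_extractor`.
#' @export
feature_extractor <- function(in_channels = 3,
                              provenance = c("random_seeded", "identity"),
                              seed = 1) {
  provenance <- match.arg(provenance)
  params <- if (provenance == "identity") {
    w <- array(0, c(1, 1, in_channels, in_channels))
    for (i in seq_len(in_channels)) w[1, 1, i, i] <- 1
    list(f1_w = w, f1_b = numeric(in_channels))
  } else {
    with_seed(seed, {
      k1 <- init_conv(3, 3, in_channels, 8)
      k2 <- init_conv(3, 3, 8, 16)
      list(f1_w = k1$w, f1_b = k1$b, f2_w = k2$w, f2_b = k2$b)
    })
  }
  structure(list(in_channels = in_channels, provenance = provenance,
                 seed = seed, params = params),
            class = "feature_extractor")
}

# Feature maps at every tap (with caches for backward).
fx_forward <- function(fx, x) {
  if (fx$provenance == "identity") {
    c1 <- op_conv(x, fx$params$f1_w, fx$params$f1_b, stride = 1L, pad = 0L)
    return(list(taps = list(tap1 = c1$y), cache = list(c1 = c1$cache)))
  }
  c1 <- op_conv(x, fx$params$f1_w, fx$params$f1_b)
  a1 <- op_relu(c1$y)
  c2 <- op_conv(a1$y, fx$params$f2_w, fx$params$f2_b, stride = 2L)
  a2 <- op_relu(c2$y)
  list(taps = list(tap1 = a1$y, tap2 = a2$y),
       cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                    a2 = a2$cache))
}

# Input gradient given gradients w.r.t. each tap (parameters are frozen).
fx_backward <- function(fx, cache, dtaps) {
  if (fx$provenance == "identity") {
    return(bwd_conv(cache$c1, dtaps$tap1)$dx)
  }
  d2 <- bwd_relu(cache$a2, dtaps$tap2)
  dx2 <- bwd_conv(cache$c2, d2)$dx
  d1 <- bwd_relu(cache$a1, dtaps$tap1 + dx2)
  bwd_conv(cache$c1, d1)$dx
}
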