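# Minimal layer operations with explicit forward/backward passes.
#
# Tensors are plain H x W x C arrays. Each op_* function returns
# list(y, cache); the matching bwd_* takes the cache and the upstream
# gradient and returns the input gradient (plus parameter gradients where
# applicable). Convolution runs through the compiled im2col/gemm kernels.

op_conv <- function(x, w, b, stride = 1L, pad = 1L, keep_cols = TRUE) {
  f <- .conv2d_fwd(x, w, b, as.integer(stride), as.integer(pad), keep_cols)
  list(y = f$y, cache = list(x = x, w = w, stride = stride, pad = pad,
                             cols = f$cols))
}

bwd_conv <- function(cache, dy) {
  g <- .conv2d_bwd(cache$x, cache$w, dy, as.integer(cache$stride),
                   as.integer(cache$pad), cache$cols)
  list(dx = g$dx, dw = g$dw, db = g$db)
}

op_lrelu <- function(x, alpha = 0.2) {
  scale <- alpha + (1 - alpha) * (x > 0)
  list(y = x * scale, cache = list(scale = scale))
}

bwd_lrelu <- function(cache, dy) dy * cache$scale

op_relu <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  list(y = y, cache = list(pos = x > 0))
}

bwd_relu <- function(cache, dy) {
  dx <- dy * cache$pos
  dim(dx) <- dim(dy)
  dx
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = list(y = y))
}

bwd_sigmoid <- function(cache, dy) dy * cache$y * (1 - cache$y)

# Instance normalisation (no learned affine): each channel normalised to
# zero mean, unit variance over its spatial extent.
op_instnorm <- function(x, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  inv_sd <- 1 / sqrt(v + eps)
  yh <- (xm - rep(mu, each = n)) * rep(inv_sd, each = n)
  y <- array(yh, d)
  list(y = y, cache = list(yh = yh, inv_sd = inv_sd, d = d, n = n))
}

bwd_instnorm <- function(cache, dy) {
  d <- cache$d
  n <- cache$n
  dym <- matrix(dy, n, d[3])
  m_dy <- colMeans(dym)
  m_dyyh <- colMeans(dym * cache$yh)
  dx <- (dym - rep(m_dy, each = n) - cache$yh * rep(m_dyyh, each = n)) *
    rep(cache$inv_sd, each = n)
  array(dx, d)
}

# 2x average pooling (H, W must be even).
op_avgpool2 <- function(x) {
  d <- dim(x)
  y <- (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
        x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
        x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
        x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
  list(y = y, cache = list(d = d))
}

bwd_avgpool2 <- function(cache, dy) {
  d <- cache$d
  dx <- array(0, d)
  q <- dy / 4
  dx[seq(1, d[1], 2), seq(1, d[2], 2), ] <- q
  dx[seq(2, d[1], 2), seq(1, d[2], 2), ] <- q
  dx[seq(1, d[1], 2), seq(2, d[2], 2), ] <- q
  dx[seq(2, d[1], 2), seq(2, d[2], 2), ] <- q
  dx
}

avgpool2 <- function(x) op_avgpool2(x)$y

# Nearest-neighbour 2x upsampling.
op_upnearest2 <- function(x) {
  d <- dim(x)
  idx_r <- rep(seq_len(d[1]), each = 2)
  idx_c <- rep(seq_len(d[2]), each = 2)
  y <- x[idx_r, idx_c, , drop = FALSE]
  list(y = y, cache = list(d = d))
}

bwd_upnearest2 <- function(cache, dy) {
  d <- cache$d
  dy[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , drop = FALSE] +
    dy[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , drop = FALSE] +
    dy[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , drop = FALSE] +
    dy[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , drop = FALSE]
}

op_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  list(y = y, cache = list(ca = da[3]))
}

bwd_concat <- function(cache, dy) {
  list(da = dy[, , seq_len(cache$ca), drop = FALSE],
       db = dy[, , -seq_len(cache$ca), drop = FALSE])
}

# He-style seeded initialisation for a conv weight kh x kw x cin x cout.
init_conv <- function(kh, kw, cin, cout, gain = 2) {
  w <- array(rnorm(kh * kw * cin * cout, 0, sqrt(gain / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

# --- Adam optimiser -------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Order-insensitive checksum of a parameter list, used to compare model
# states across training phases.
param_checksum <- function(params) {
  v <- unlist(params[order(names(params))], use.names = FALSE)
  c(sum = sum(v), sumsq = sum(v^2), n = length(v))
}

# Central finite-difference gradient of scalar-valued f at x (array).
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
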