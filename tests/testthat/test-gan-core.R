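# Loss functions, generator/discriminator architectures, and gradient
# correctness against central finite differences.

test_that("pixel MSE matches hand-computed values and is symmetric", {
  pred <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(loss_mse(pred, matrix(0, 2, 2)), 0.5)
  expect_equal(loss_mse(pred, pred), 0)
  a <- array(runif(8), c(2, 2, 2)); b <- array(runif(8), c(2, 2, 2))
  expect_equal(loss_mse(a, b), loss_mse(b, a))
  expect_error(loss_mse(a, matrix(0, 2, 2)), "shape")
})

test_that("perceptual loss reduces to MSE under the identity extractor", {
  fx_id <- feature_extractor(3, "identity")
  a <- array(runif(4 * 4 * 3), c(4, 4, 3))
  b <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(loss_perceptual(a, b, fx_id), loss_mse(a, b),
               tolerance = 1e-12)
  expect_equal(loss_perceptual(a, a, fx_id), 0)
  fx_rand <- feature_extractor(3, "random_seeded", seed = 4)
  expect_equal(loss_perceptual(a, a, fx_rand), 0)
  expect_gte(loss_perceptual(a, b, fx_rand), 0)
  # extractor is deterministic given provenance and seed
  expect_identical(feature_extractor(3, seed = 4)$params, fx_rand$params)
})

test_that("least-squares adversarial loss matches hand values", {
  ones <- list(array(1, c(2, 2, 1)), array(1, c(1, 1, 1)))
  expect_equal(loss_adversarial(ones, 1), 0)
  half <- list(array(0.5, c(2, 2, 1)), array(0.5, c(1, 1, 1)))
  expect_equal(loss_adversarial(half, 1), 0.25)
  # a perfect discriminator scores real 1 and fake 0 with zero loss
  expect_equal(loss_adversarial(ones, 1) + loss_adversarial(
    lapply(ones, function(s) s * 0), 0), 0)
})

test_that("staining objective composes its terms with alpha and gamma", {
  fx <- feature_extractor(3, "identity")
  pred <- array(runif(4 * 4 * 3), c(4, 4, 3))
  target <- array(runif(4 * 4 * 3), c(4, 4, 3))
  scores <- list(array(0.3, c(2, 2, 1)), array(0.7, c(1, 1, 1)))
  w0 <- loss_weights(alpha = 0, gamma = 0)
  l0 <- g1_total_loss(pred, target, scores, fx, w0)
  expect_equal(l0$total, l0$adversarial)
  wd <- loss_weights()
  expect_equal(wd$alpha, 0.01)
  expect_equal(wd$gamma, 0.005)
  expect_equal(wd$lambda_cyc, 10)
  ld <- g1_total_loss(pred, target, scores, fx, wd)
  expect_equal(ld$total,
               ld$adversarial + 0.01 * ld$mse + 0.005 * ld$perceptual,
               tolerance = 1e-12)
  # linearity: doubling alpha doubles the MSE contribution
  l2 <- g1_total_loss(pred, target, scores, fx,
                      loss_weights(alpha = 0.02, gamma = 0.005))
  expect_equal(l2$total - ld$total, 0.01 * ld$mse, tolerance = 1e-12)
  expect_error(loss_weights(alpha = -1), "nonnegative")
})

test_that("cycle loss is the L1 metric with exact hand values", {
  x <- array(1, c(3, 3, 2))
  expect_equal(loss_cycle(x, array(0, c(3, 3, 2))), 1)
  expect_equal(loss_cycle(x, x), 0)
  a <- array(runif(18), c(3, 3, 2))
  b <- array(runif(18), c(3, 3, 2))
  cc <- array(runif(18), c(3, 3, 2))
  expect_lte(loss_cycle(a, cc), loss_cycle(a, b) + loss_cycle(b, cc) + 1e-12)
  tot <- cycle_total_loss(c(0.2, 0.3), c(0.1, 0.05), loss_weights())
  expect_equal(tot$total, 0.5 + 10 * 0.15)
  tot0 <- cycle_total_loss(c(0.2, 0.3), c(0.1, 0.05),
                           loss_weights(lambda_cyc = 0))
  expect_equal(tot0$total, 0.5)
  # scaling both cycle terms scales their contribution exactly
  tot2 <- cycle_total_loss(c(0.2, 0.3), 3 * c(0.1, 0.05), loss_weights())
  expect_equal(tot2$total - tot0$total, 10 * 3 * 0.15, tolerance = 1e-12)
})

test_that("generator maps to [0,1] at the input size, deterministically per seed", {
  spec <- generator_spec(7, 3, base_width = 8, depth = 2, seed = 11)
  g <- build_generator(spec)
  x <- array(runif(64 * 64 * 7), c(64, 64, 7))
  y <- predict(g, x)
  expect_equal(dim(y), c(64L, 64L, 3L))
  expect_true(all(y >= 0 & y <= 1))
  g2 <- build_generator(spec)
  expect_identical(srstain:::param_checksum(g$params),
                   srstain:::param_checksum(g2$params))
  expect_identical(g$params, g2$params)
  # output is in [0,1] for any input scale (activation contract)
  yy <- predict(g, x * 50 - 25)
  expect_true(all(yy >= 0 & yy <= 1))
  expect_error(predict(g, array(0, c(30, 30, 7))), "divisible")
})

test_that("doubling base width roughly quadruples the parameter count", {
  n1 <- n_params(build_generator(generator_spec(7, 3, 8, 2, seed = 1)))
  n2 <- n_params(build_generator(generator_spec(7, 3, 16, 2, seed = 1)))
  expect_gt(n2 / n1, 3.4)
  expect_lt(n2 / n1, 4.1)
})

test_that("multi-scale discriminators share layout and honour the scale contract", {
  spec <- discriminator_spec(3, layers = 3, base_width = 8, seed = 5)
  d <- build_discriminators(spec)
  # identical seeds give identical initial weights across the two scales
  expect_identical(d$d1, d$d2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  s <- discriminators_score(d, x)
  expect_length(s, 2)
  expect_equal(dim(s[[2]])[1], dim(s[[1]])[1] / 2)
  # the scale-2 path is exactly the scale-1 architecture applied to the
  # 2x average-pooled input
  pooled <- srstain:::avgpool2(x)
  direct <- srstain:::disc_forward(spec, d$d2, pooled)$y
  expect_identical(s[[2]], direct)
  expect_error(discriminators_score(d, array(0, c(8, 8, 3))),
               "receptive field")
})

test_that("conv, instance-norm and pooling backward passes match finite differences", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3, 3, 2, 3))
  b <- rnorm(3)
  target <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  loss_of <- function(xx, ww, bb) {
    y <- srstain:::.conv2d_fwd(xx, ww, bb, 2L, 1L, FALSE)$y
    loss_mse(y, target)
  }
  fwd <- srstain:::op_conv(x, w, b, stride = 2L, pad = 1L)
  gr <- srstain:::bwd_conv(fwd$cache, srstain:::grad_mse(fwd$y, target))
  ngx <- srstain:::numeric_gradient(function(v) loss_of(v, w, b), x)
  ngw <- srstain:::numeric_gradient(function(v) loss_of(x, v, b), w)
  ngb <- srstain:::numeric_gradient(function(v) loss_of(x, w, v), b)
  expect_lt(max(abs(gr$dx - ngx)) / max(abs(ngx)), 1e-4)
  expect_lt(max(abs(gr$dw - ngw)) / max(abs(ngw)), 1e-4)
  expect_lt(max(abs(gr$db - ngb)) / max(abs(ngb)), 1e-4)
  # instance norm
  xi <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  ti <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  fin <- srstain:::op_instnorm(xi)
  gin <- srstain:::bwd_instnorm(fin$cache, srstain:::grad_mse(fin$y, ti))
  nin <- srstain:::numeric_gradient(function(v) {
    loss_mse(srstain:::op_instnorm(v)$y, ti)
  }, xi)
  expect_lt(max(abs(gin - nin)) / max(abs(nin)), 1e-4)
  # average pooling
  xp <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  tp <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  fp <- srstain:::op_avgpool2(xp)
  gp <- srstain:::bwd_avgpool2(fp$cache, srstain:::grad_mse(fp$y, tp))
  np <- srstain:::numeric_gradient(function(v) {
    loss_mse(srstain:::op_avgpool2(v)$y, tp)
  }, xp)
  expect_lt(max(abs(gp - np)) / max(abs(np)), 1e-4)
})

test_that("full generator and loss gradients match finite differences on toy tensors", {
  g <- build_generator(generator_spec(2, 1, base_width = 2, depth = 1,
                                      seed = 3))
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  target <- array(runif(4 * 4 * 1), c(4, 4, 1))
  fwd <- srstain:::generator_forward(g, x)
  bk <- srstain:::generator_backward(g, fwd$cache,
                                     srstain:::grad_mse(fwd$y, target))
  # input gradient
  ng <- srstain:::numeric_gradient(function(v) {
    loss_mse(srstain:::generator_forward(g, v)$y, target)
  }, x, eps = 1e-5)
  expect_lt(max(abs(bk$dx - ng)) / max(abs(ng)), 1e-4)
  # parameter gradients for every parameter tensor
  for (nm in names(g$params)) {
    npg <- srstain:::numeric_gradient(function(v) {
      g2 <- g; g2$params[[nm]] <- v
      loss_mse(srstain:::generator_forward(g2, x)$y, target)
    }, g$params[[nm]], eps = 1e-5)
    denom <- max(abs(npg), 1e-8)
    expect_lt(max(abs(bk$grads[[nm]] - npg)) / denom, 1e-4)
  }
})

test_that("perceptual and adversarial gradients match finite differences", {
  fx <- feature_extractor(2, "random_seeded", seed = 9)
  pred <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  target <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  gp <- srstain:::grad_perceptual(pred, target, fx)
  np <- srstain:::numeric_gradient(function(v) {
    loss_perceptual(v, target, fx)
  }, pred)
  expect_lt(max(abs(gp - np)) / max(abs(np)), 1e-4)
  # adversarial gradient through a small discriminator
  spec <- discriminator_spec(2, layers = 2, base_width = 4, seed = 2)
  d <- build_discriminators(spec)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  md <- srstain:::msd_forward(d, x)
  gadv <- srstain:::msd_backward(d, md$cache,
                                 srstain:::grad_adversarial(md$scores, 1),
                                 want_params = FALSE)$dx
  nadv <- srstain:::numeric_gradient(function(v) {
    loss_adversarial(srstain:::msd_forward(d, v)$scores, 1)
  }, x)
  expect_lt(max(abs(gadv - nadv)) / max(abs(nadv)), 1e-4)
  # cycle (L1) gradient away from the non-differentiable zero set
  xa <- array(rnorm(3 * 3 * 1) + 3, c(3, 3, 1))
  xr <- array(rnorm(3 * 3 * 1) - 3, c(3, 3, 1))
  gc_ <- srstain:::grad_cycle(xa, xr)
  nc <- srstain:::numeric_gradient(function(v) loss_cycle(xa, v), xr)
  expect_lt(max(abs(gc_ - nc)), 1e-6)
})
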