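# Gradient correctness of the reverse-mode tape against central finite
# differences, op by op and through a composite graph.

num_grad <- function(f, x, idx, eps = 1e-6) {
  xp <- x; xp[idx] <- xp[idx] + eps
  xm <- x; xm[idx] <- xm[idx] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# scalar-valued wrapper: sum of weighted output, so dL/dy is a known array
check_op <- function(build, x, n_idx = 4, tol = 1e-6, seed = 1) {
  set.seed(seed)
  tape <- semreg:::ad_tape()
  xn <- semreg:::ad_leaf(tape, x)
  out <- build(tape, xn)
  wts <- array(rnorm(length(out$value)), dim(out$value) %||% NULL)
  loss <- semreg:::ad_node(tape, sum(wts * out$value), list(out),
                           function(g) list(g * wts))
  semreg:::ad_backward(tape, loss)
  f <- function(xx) {
    t2 <- semreg:::ad_tape()
    sum(wts * build(t2, semreg:::ad_leaf(t2, xx))$value)
  }
  idxs <- sample(length(x), n_idx)
  for (idx in idxs) {
    ng <- num_grad(f, x, idx)
    expect_lt(abs(ng - xn$grad[idx]) / max(1, abs(ng)), tol)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("conv, pooling, resize and upsample gradients match finite differences", {
  set.seed(42)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- matrix(rnorm(9 * 3 * 2, sd = 0.3), 27, 2)
  b <- rnorm(2)
  check_op(function(t, xn)
    semreg:::ad_conv(t, xn, semreg:::ad_leaf(t, w), semreg:::ad_leaf(t, b),
                     3L, 3L, 1L, 1L), x)
  check_op(function(t, xn)
    semreg:::ad_conv(t, xn, semreg:::ad_leaf(t, w), semreg:::ad_leaf(t, b),
                     3L, 3L, 2L, 1L), x)
  # conv weight gradient
  tape <- semreg:::ad_tape()
  xn <- semreg:::ad_leaf(tape, x); wn <- semreg:::ad_leaf(tape, w)
  out <- semreg:::ad_conv(tape, xn, wn, semreg:::ad_leaf(tape, b), 3L, 3L, 1L, 1L)
  wts <- array(rnorm(length(out$value)), dim(out$value))
  loss <- semreg:::ad_node(tape, sum(wts * out$value), list(out),
                           function(g) list(g * wts))
  semreg:::ad_backward(tape, loss)
  fW <- function(ww) {
    t2 <- semreg:::ad_tape()
    sum(wts * semreg:::ad_conv(t2, semreg:::ad_leaf(t2, x),
                               semreg:::ad_leaf(t2, ww),
                               semreg:::ad_leaf(t2, b), 3L, 3L, 1L, 1L)$value)
  }
  for (idx in c(1, 13, 54)) {
    ng <- num_grad(fW, w, idx)
    expect_lt(abs(ng - wn$grad[idx]) / max(1, abs(ng)), 1e-6)
  }

  check_op(function(t, xn) semreg:::ad_avgpool(t, xn, 3L), x)
  check_op(function(t, xn) semreg:::ad_upsample_nearest(t, xn, 2L), x)
  check_op(function(t, xn) semreg:::ad_resize_bilinear(t, xn, 16L, 16L), x)
  check_op(function(t, xn) semreg:::ad_leaky_relu(t, xn), x)
  check_op(function(t, xn) semreg:::ad_softmax(t, xn), x)
})

test_that("warp gradients (source and field) match finite differences", {
  set.seed(5)
  src <- array(box_filter_oracle(matrix(runif(100), 10, 10), 3, 2), c(10, 10, 1))
  fld <- random_smooth_field(10, max_disp = 1.5, seed = 3)
  # wrt field
  tape <- semreg:::ad_tape()
  sn <- semreg:::ad_leaf(tape, src); fn <- semreg:::ad_leaf(tape, fld)
  out <- semreg:::ad_warp(tape, sn, fn)
  wts <- array(rnorm(length(out$value)), dim(out$value))
  loss <- semreg:::ad_node(tape, sum(wts * out$value), list(out),
                           function(g) list(g * wts))
  semreg:::ad_backward(tape, loss)
  f_fld <- function(ff) sum(wts * warp_image(src, ff, "bilinear"))
  f_src <- function(ss) sum(wts * warp_image(ss, fld, "bilinear"))
  for (idx in c(15, 57, 120, 190)) {
    ng <- num_grad(f_fld, fld, idx)
    expect_lt(abs(ng - fn$grad[idx]), 1e-5)
  }
  for (idx in c(5, 44, 99)) {
    ng <- num_grad(f_src, src, idx)
    expect_lt(abs(ng - sn$grad[idx]), 1e-5)
  }
})

test_that("loss-op gradients match finite differences", {
  set.seed(8)
  L <- 3L
  probs <- array(runif(6 * 6 * L, 0.05, 1), c(6, 6, L))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), L), dim(probs))
  truth <- matrix(sample(0:(L - 1), 36, TRUE), 6, 6)
  w <- c(1.2, 0.8, 1.0)
  tape <- semreg:::ad_tape()
  pn <- semreg:::ad_leaf(tape, probs)
  loss <- semreg:::ad_weighted_ce(tape, pn, truth, w)
  semreg:::ad_backward(tape, loss)
  f <- function(pp) {
    t2 <- semreg:::ad_tape()
    semreg:::ad_weighted_ce(t2, semreg:::ad_leaf(t2, pp), truth, w)$value
  }
  for (idx in c(2, 40, 77, 100)) {
    ng <- num_grad(f, probs, idx)
    expect_lt(abs(ng - (pn$grad[idx] %||% 0)), 1e-5)
  }

  target <- array(runif(6 * 6 * L), c(6, 6, L))
  x <- array(runif(6 * 6 * L), c(6, 6, L))
  tape <- semreg:::ad_tape()
  xn <- semreg:::ad_leaf(tape, x)
  loss <- semreg:::ad_weighted_l1(tape, target, xn, w)
  semreg:::ad_backward(tape, loss)
  f <- function(xx) {
    t2 <- semreg:::ad_tape()
    semreg:::ad_weighted_l1(t2, target, semreg:::ad_leaf(t2, xx), w)$value
  }
  for (idx in c(3, 50, 90)) {
    ng <- num_grad(f, x, idx)
    expect_lt(abs(ng - xn$grad[idx]), 1e-5)
  }
})

test_that("one optimizer step on a fixed mini-batch reduces the total loss", {
  set.seed(31)
  spec <- scene_spec(c(32, 32), max_displacement = 4)
  pairs <- lapply(1:2, function(s) generate_pair(spec, 100 + s))
  cfg <- train_config(kernel1 = 15L, kernel2 = 7L, unet_channels = 4L,
                      regnet_channels = 4L, lr = 0.01, seed = 1)
  models <- tiny_models(seed = 2)
  w <- class_weights(lapply(pairs, `[[`, "fixed_labels"), 4L)
  loss_of <- function(m) mean(sapply(pairs, function(p)
    semreg:::pair_step(m, p, w, cfg, compute_grads = FALSE)$total))
  l0 <- loss_of(models)
  adam <- semreg:::new_adam()
  theta <- semreg:::theta_from_models(models, cfg)
  gacc <- NULL
  for (p in pairs)
    gacc <- semreg:::accumulate_grads(gacc,
              semreg:::pair_step(models, p, w, cfg)$grads)
  gacc <- lapply(gacc, function(g) g / length(pairs))
  theta <- semreg:::adam_update(adam, theta, gacc, cfg$lr, cfg$beta1)
  models2 <- semreg:::models_from_theta(models, theta, cfg)
  expect_lt(loss_of(models2), l0)
})
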