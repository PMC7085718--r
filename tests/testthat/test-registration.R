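# Registration networks and cascade orchestration.

test_that("cascade parameter budget and control-grid output contract hold", {
  rc <- regnet_config(4L)
  n1 <- build_regnet(rc, 1L); n2 <- build_regnet(rc, 2L)
  total <- count_parameters(n1) + count_parameters(n2)
  expect_gte(total, 1.8e6)
  expect_lte(total, 2.8e6)
  # single-step variant matches the cascade budget
  ns <- build_regnet(rc, 1L, base_channels = 68L)
  expect_gte(count_parameters(ns), 1.8e6)
  expect_lte(count_parameters(ns), 2.8e6)

  expect_equal(rc$spacing1, 8L)
  expect_equal(rc$spacing2, 4L)
  expect_equal(regnet_config(4L, 19L, 11L)$spacing1, 8L)
  expect_equal(regnet_config(4L, 5L, 3L)$spacing2, 2L)
  expect_error(regnet_config(4L, 7L, 15L), "coarse")
  expect_error(regnet_config(4L, 8L, 4L), "odd")

  # control grid is coarser than the feature grid, 2 channels
  set.seed(2)
  rc4 <- regnet_config(4L, base_channels = 4L)
  net <- build_regnet(rc4, 1L)
  tape <- semreg:::ad_tape()
  pn <- semreg:::param_nodes(tape, net$params)
  x <- semreg:::ad_leaf(tape, array(runif(32 * 32 * 8), c(32, 32, 8)))
  ctrl <- semreg:::regnet_forward(tape, net, pn, x)
  expect_equal(dim(ctrl$value), c(4L, 4L, 2L))
})

test_that("zero-initialized heads give the identity transform", {
  set.seed(3)
  models <- tiny_models()
  ff <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  fm <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  res <- two_step_register(ff, fm, models$net1, models$net2)
  expect_true(all(res$v1 == 0))
  expect_true(all(res$v2 == 0))
  expect_true(all(res$v == 0))
  img <- matrix(runif(64 * 64), 64, 64)
  res2 <- two_step_register(ff, fm, models$net1, models$net2,
                            moving_image = img)
  expect_lt(max(abs(res2$warped_moving - img)), 1e-6)

  rs <- single_step_register(ff, fm, models$net1, moving_image = img)
  expect_true(all(rs$v == 0))
  expect_null(rs$v2)
})

test_that("combined field reduces to v1 when v2 is zero, in both modes", {
  set.seed(4)
  models <- tiny_models(seed = 5)
  # give net1 a non-trivial head, keep net2 at zero
  models$net1$params[["w.head"]][] <- rnorm(
    length(models$net1$params[["w.head"]]), sd = 0.05)
  img1 <- matrix(runif(64 * 64), 64, 64)
  img2 <- matrix(runif(64 * 64), 64, 64)
  ff <- feature_forward(models$unet, img1)
  fm <- feature_forward(models$unet, img2)
  for (mode in c("transform", "additive")) {
    res <- two_step_register(ff, fm, models$net1, models$net2,
                             combine_mode = mode)
    expect_false(all(res$v1 == 0))
    expect_equal(res$v, res$v1, tolerance = 1e-12)
  }
})

test_that("feature scale invariance: renormalized probabilities give the same field", {
  set.seed(6)
  models <- tiny_models(seed = 7)
  models$net1$params[["w.head"]][] <- rnorm(
    length(models$net1$params[["w.head"]]), sd = 0.05)
  ff <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  fm <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  renorm <- function(p) { q <- 3 * p; q / array(rep(apply(q, c(1, 2), sum),
                                                    dim(p)[3]), dim(p)) }
  r1 <- two_step_register(ff, fm, models$net1, models$net2)
  r2 <- two_step_register(renorm(ff), renorm(fm), models$net1, models$net2)
  expect_equal(r1$v, r2$v, tolerance = 1e-10)
})

test_that("diffeomorphic mode exponentiates the predicted velocities", {
  set.seed(8)
  models <- tiny_models(seed = 9)
  models$net1$params[["w.head"]][] <- rnorm(
    length(models$net1$params[["w.head"]]), sd = 0.2)
  models$net2$params[["w.head"]][] <- rnorm(
    length(models$net2$params[["w.head"]]), sd = 0.2)
  ff <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  fm <- feature_forward(models$unet, matrix(runif(64 * 64), 64, 64))
  rd <- two_step_register(ff, fm, models$net1, models$net2,
                          diffeomorphic = TRUE)
  js <- jacobian_summary(rd$v[3:62, 3:62, , drop = FALSE])
  expect_equal(js$negative_fraction, 0)
})

test_that("weight sharing across the cascade uses one parameter set", {
  set.seed(10)
  spec <- scene_spec(c(32, 32), max_displacement = 3)
  pairs <- lapply(1:3, function(s) generate_pair(spec, 600 + s))
  cfg <- train_config(epochs = 1L, batch_size = 3L, unet_channels = 4L,
                      regnet_channels = 4L, shared_regnet_weights = TRUE,
                      seed = 2)
  ck <- train_registration(pairs, cfg)
  expect_identical(ck$models$net1$params, ck$models$net2$params)
  expect_error(train_config(two_step = FALSE, shared_regnet_weights = TRUE),
               "two_step")
})
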