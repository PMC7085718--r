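# Semantic feature extraction: architecture contract, class weights,
# weighted cross-entropy.

test_that("feature net meets the size/shape/normalization contract", {
  net <- build_feature_net(8L)
  expect_gte(count_parameters(net), 150000)
  expect_lte(count_parameters(net), 250000)

  net4 <- build_feature_net(4L, base_channels = 6L)
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  probs <- feature_forward(net4, img)
  expect_equal(dim(probs), c(32L, 32L, 4L))
  expect_true(all(probs >= 0))
  expect_lt(max(abs(apply(probs, c(1, 2), sum) - 1)), 1e-5)

  expect_error(feature_forward(net4, matrix(0, 60, 64)), "divisible by 8")
  expect_error(build_feature_net(1L), "num_labels")
})

test_that("class weights follow sqrt inverse frequency with mean 1", {
  lab <- matrix(0L, 10, 10)
  lab[1:5, ] <- 1L
  expect_equal(class_weights(lab, 2L), c(1, 1))

  lab2 <- matrix(0L, 10, 10)
  lab2[1:2, ] <- 1L  # frequencies 0.8 / 0.2
  w <- class_weights(lab2, 2L)
  expect_equal(w[2] / w[1], sqrt(0.8 / 0.2), tolerance = 1e-12)
  expect_equal(mean(w), 1)

  lab4 <- matrix(rep(0:3, each = 25), 10, 10)
  expect_equal(class_weights(lab4, 4L), rep(1, 4))

  expect_error(class_weights(lab2, 3L), "never occur")
  expect_silent(class_weights(lab2, 3L, floor_count = 1L))
})

test_that("semantic loss matches closed-form cases and scales linearly in w", {
  L <- 4L
  truth <- matrix(sample(0:(L - 1), 64, TRUE), 8, 8)
  hot <- one_hot(truth, L)
  expect_lt(semantic_loss(hot, truth, rep(1, L)), 1e-6)

  unif <- array(1 / L, c(8, 8, L))
  expect_equal(semantic_loss(unif, truth, rep(1, L)), log(L),
               tolerance = 1e-12)
  expect_equal(log(4), 1.3862944, tolerance = 1e-6)

  set.seed(2)
  probs <- array(runif(8 * 8 * L, 0.1, 1), c(8, 8, L))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), L), dim(probs))
  w <- runif(L, 0.5, 2)
  expect_equal(semantic_loss(probs, truth, 2 * w),
               2 * semantic_loss(probs, truth, w), tolerance = 1e-12)
  expect_error(semantic_loss(probs, truth[1:4, ], w), "mismatch")
})

test_that("weighted loss penalizes all-background collapse more than uniform", {
  lab <- matrix(0L, 16, 16)
  lab[6:10, 6:10] <- 1L  # rare foreground
  w <- class_weights(lab, 2L)
  collapse <- array(0, c(16, 16, 2)); collapse[, , 1] <- 1  # always background
  balanced <- array(0.5, c(16, 16, 2))
  # weighting must increase the relative cost of majority-class collapse
  ratio_w <- semantic_loss(collapse, lab, w) / semantic_loss(balanced, lab, w)
  ratio_u <- semantic_loss(collapse, lab, c(1, 1)) /
             semantic_loss(balanced, lab, c(1, 1))
  expect_gt(ratio_w, ratio_u)
})

test_that("semantic loss decreases when training the U-Net alone", {
  set.seed(12)
  spec <- scene_spec(c(32, 32), max_displacement = 3)
  pairs <- lapply(1:4, function(s) generate_pair(spec, 200 + s))
  w <- class_weights(lapply(pairs, `[[`, "fixed_labels"), 4L)
  net <- build_feature_net(4L, 6L)
  ds <- semreg:::downsample_labels
  val_loss <- function(net) mean(sapply(pairs, function(p)
    semantic_loss(feature_forward(net, p$fixed), ds(p$fixed_labels), w)))
  l0 <- val_loss(net)
  adam <- semreg:::new_adam()
  for (it in 1:8) {
    for (p in pairs) {
      tape <- semreg:::ad_tape()
      pn <- semreg:::param_nodes(tape, net$params)
      probs <- semreg:::unet_forward(tape, net, pn, semreg:::ad_leaf(tape, semreg:::as_cube(p$fixed)))
      loss <- semreg:::ad_weighted_ce(tape, probs, ds(p$fixed_labels), w)
      semreg:::ad_backward(tape, loss)
      gs <- setNames(lapply(pn, function(n) n$grad), names(net$params))
      net$params <- semreg:::adam_update(adam, net$params, gs, 0.003, 0.9)
    }
  }
  expect_lt(val_loss(net), l0)
})
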