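# Geometric core: densification, warping, smoothing, composition,
# scaling-and-squaring, Jacobians.

test_that("densify preserves constants and rejects bad parameters", {
  cg <- control_grid(array(3.25, c(8, 8, 2)), 8L)
  fld <- densify(cg, c(64, 64), 15L)
  expect_lt(max(abs(fld - 3.25)), 1e-5)
  expect_equal(dim(fld), c(64L, 64L, 2L))

  zg <- control_grid(array(0, c(4, 4, 2)), 4L)
  expect_true(all(densify(zg, c(16, 16), 7L) == 0))

  expect_error(densify(cg, c(64, 64), 4L), "odd")
  small <- control_grid(array(0, c(2, 2, 2)), 4L)
  expect_error(densify(small, c(8, 8), 15L), "larger")
  expect_error(densify(cg, c(32, 32), 15L), "inconsistent")
})

test_that("densify impulse response equals the triple box-filter oracle", {
  s <- 4L; k <- 5L
  vals <- array(0, c(8, 8, 2))
  vals[4, 5, 1] <- 1
  fld <- densify(control_grid(vals, s), c(32, 32), k)
  # oracle: replicate upsampling of the impulse then three explicit box passes
  up <- matrix(0, 32, 32)
  up[(4L - 1L) * s + 1:s, (5L - 1L) * s + 1:s] <- 1
  expect_lt(max(abs(fld[, , 1] - box_filter_oracle(up, k, passes = 3))), 1e-12)
  expect_true(all(fld[, , 2] == 0))
})

test_that("densify is linear in the control values", {
  set.seed(11)
  g1 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  g2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  d <- function(v) densify(control_grid(v, 8L), c(64, 64), 15L)
  expect_lt(max(abs(d(2 * g1 - 3 * g2) - (2 * d(g1) - 3 * d(g2)))), 1e-10)
})

test_that("warping matches identity, translation, and bilinear ramp cases", {
  set.seed(2)
  img <- matrix(runif(24 * 24), 24, 24)
  zf <- zero_field(24)
  expect_identical(warp_image(img, zf, "nearest"), img)
  expect_lt(max(abs(warp_image(img, zf, "bilinear") - img)), 1e-6)

  tf <- zf; tf[, , 1] <- 3  # Dx = 3: output(x) = source(x + 3)
  wt <- warp_image(img, tf, "nearest")
  expect_equal(wt[, 1:21], img[, 4:24])

  ramp <- matrix(rep(0:23, each = 24), 24, 24)  # source(x, y) = x
  hf <- zf; hf[, , 1] <- 0.5
  wr <- warp_image(ramp, hf, "bilinear")
  expect_equal(wr[, 1:23], ramp[, 1:23] + 0.5, tolerance = 1e-12)

  expect_error(warp_image(img[1:10, ], zf), "shape")
})

test_that("field smoothing preserves constants and matches the box oracle", {
  cf <- zero_field(16) + 1.5
  expect_equal(smooth_field(cf, 3L, 2L), cf)
  set.seed(3)
  rf <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_equal(smooth_field(rf, 1L, 5L), rf)

  imp <- zero_field(16)
  imp[7, 9, 1] <- 2
  sm <- smooth_field(imp, 3L, 2L)
  expect_lt(max(abs(sm[, , 1] - box_filter_oracle(imp[, , 1], 3, 2))), 1e-12)
})

test_that("composition handles constants, zero inner, and both modes", {
  t1 <- zero_field(16); t1[, , 1] <- 1.5; t1[, , 2] <- -0.5
  t2 <- zero_field(16); t2[, , 1] <- 0.75; t2[, , 2] <- 1
  for (mode in c("additive", "transform")) {
    comp <- compose_fields(t2, t1, mode)
    expect_lt(max(abs(comp[3:13, 3:13, 1] - 2.25)), 1e-6)
    expect_lt(max(abs(comp[3:13, 3:13, 2] - 0.5)), 1e-6)
  }
  v <- random_smooth_field(16, max_disp = 2, seed = 5)
  expect_equal(compose_fields(v, zero_field(16), "additive"), v)
  expect_equal(compose_fields(v, zero_field(16), "transform"), v)
  # additive mode commutes
  w <- random_smooth_field(16, max_disp = 2, seed = 6)
  expect_equal(compose_fields(v, w, "additive"), compose_fields(w, v, "additive"))
})

test_that("transform-mode composition equals two-stage warping", {
  # linear fields and a linear test image: bilinear sampling is exact on
  # both, so any discrepancy isolates the composition formula itself
  H <- 32L
  xs <- outer(rep(1, H), 0:(H - 1)); ys <- outer(0:(H - 1), rep(1, H))
  v1 <- zero_field(H); v1[, , 1] <- 0.04 * xs - 0.02 * ys
  v1[, , 2] <- 0.03 * ys + 0.01 * xs
  v2 <- zero_field(H); v2[, , 1] <- -0.03 * xs + 1
  v2[, , 2] <- 0.05 * xs - 0.5
  img <- (xs + 2 * ys) / (3 * (H - 1))
  two_stage <- warp_image(warp_image(img, v1), v2)
  one_stage <- warp_image(img, compose_fields(v2, v1, "transform"))
  interior <- 8:(H - 7)
  expect_lt(max(abs(two_stage[interior, interior] -
                    one_stage[interior, interior])), 1e-3)
  # and additive mode demonstrably differs for these non-constant fields
  additive <- warp_image(img, compose_fields(v2, v1, "additive"))
  expect_gt(max(abs(additive[interior, interior] -
                    two_stage[interior, interior])), 1e-4)
})

test_that("scaling and squaring: identity cases and small-velocity limit", {
  expect_equal(scaling_and_squaring(zero_field(16)), zero_field(16))
  tv <- zero_field(32); tv[, , 1] <- 2
  ss <- scaling_and_squaring(tv, 6L)
  expect_lt(max(abs(ss[5:28, 5:28, ] - tv[5:28, 5:28, ])), 1e-6)

  # ||exp(v) - v|| = O(||v||^2): shrinking v by 4 shrinks the gap ~16x
  v <- random_smooth_field(32, max_disp = 4, seed = 7)
  gap <- function(vel) max(abs(scaling_and_squaring(vel, 6L) - vel))
  g1 <- gap(v); g2 <- gap(v / 4)
  expect_lt(g2, g1 / 8)
})

test_that("Jacobian determinant matches analytic linear fields", {
  expect_equal(jacobian_determinant(zero_field(12)),
               matrix(1, 12, 12))
  H <- 24L
  a <- 0.2; b <- -0.1
  lin <- zero_field(H)
  lin[, , 1] <- outer(rep(1, H), 0:(H - 1)) * a  # Dx = a * x
  lin[, , 2] <- outer(0:(H - 1), rep(1, H)) * b  # Dy = b * y
  jd <- jacobian_determinant(lin)
  expect_lt(max(abs(jd[2:(H - 1), 2:(H - 1)] - (1 + a) * (1 + b))), 1e-10)

  neg <- zero_field(H)
  neg[, , 1] <- outer(rep(1, H), 0:(H - 1)) * -2  # Dx = -2x -> det = -1
  jn <- jacobian_determinant(neg)
  expect_lt(max(abs(jn[2:(H - 1), 2:(H - 1)] + 1)), 1e-10)
})

test_that("Jacobian determinant agrees with the independent mapping oracle", {
  for (seed in 1:3) {
    fld <- random_smooth_field(24, max_disp = 3, seed = seed)
    jd <- jacobian_determinant(fld)
    jo <- jacobian_oracle(fld)
    expect_lt(max(abs(jd - jo)), 1e-4)
  }
})

test_that("fields round-trip through serialization with a sidecar header", {
  fld <- random_smooth_field(16, max_disp = 2, seed = 4)
  path <- file.path(tempdir(), "f.rds")
  write_field(fld, path)
  expect_equal(read_field(path), fld)
  expect_true(file.exists(paste0(path, ".txt")))
})
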