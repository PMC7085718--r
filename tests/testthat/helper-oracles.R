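# Shared fixtures and independent oracles used across test files.

# deterministic smooth random field via an independent path is NOT wanted
# here: tests that need the B-spline family use the package generator; the
# oracles below are plain R re-derivations.

zero_field <- function(H, W = H) array(0, c(H, W, 2L))

# random smooth field from the B-spline family, any grid size
random_smooth_field <- function(H, W = H, max_disp = 3, seed = 1) {
  set.seed(seed)
  s <- 4L
  vals <- array(rnorm(ceiling(H / s) * ceiling(W / s) * 2),
                c(ceiling(H / s), ceiling(W / s), 2L))
  f <- densify(control_grid(vals, s), c(H, W), 7L)
  f * (max_disp / max(sqrt(f[, , 1]^2 + f[, , 2]^2)))
}

# --- convolution oracle: n passes of a normalized k x k box filter with
# replicate padding, written as an explicit double loop over pixels.
box_filter_oracle <- function(m, k, passes = 1) {
  r <- (k - 1) / 2
  H <- nrow(m); W <- ncol(m)
  for (p in seq_len(passes)) {
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      ii <- pmin(pmax(i + (-r:r), 1), H)
      jj <- pmin(pmax(j + (-r:r), 1), W)
      out[i, j] <- mean(m[ii, jj])
    }
    m <- out
  }
  m
}

# --- brute-force symmetric contour distance (all pairs, plain R)
contour_oracle <- function(a, b) {
  bound <- function(m) {
    m <- m != 0
    H <- nrow(m); W <- ncol(m)
    pts <- NULL
    for (i in 1:H) for (j in 1:W) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < H) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < W) m[i, j + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(j - 1, i - 1))  # (x, y), 0-based
    }
    pts
  }
  sa <- bound(a); sb <- bound(b)
  dmin <- function(p, set)
    min(sqrt((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2))
  tot <- sum(apply(sa, 1, dmin, set = sb)) + sum(apply(sb, 1, dmin, set = sa))
  tot / (nrow(sa) + nrow(sb))
}

# --- brute-force Jacobian oracle: independently finite-difference the
# mapping x -> x + D(x) per pixel (one-sided at borders) and take the det.
jacobian_oracle <- function(field) {
  H <- dim(field)[1]; W <- dim(field)[2]
  mapx <- outer(rep(1, H), 0:(W - 1)) + field[, , 1]
  mapy <- outer(0:(H - 1), rep(1, W)) + field[, , 2]
  out <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    jl <- max(j - 1, 1); jr <- min(j + 1, W)
    il <- max(i - 1, 1); ir <- min(i + 1, H)
    dxx <- (mapx[i, jr] - mapx[i, jl]) / (jr - jl)
    dyx <- (mapy[i, jr] - mapy[i, jl]) / (jr - jl)
    dxy <- (mapx[ir, j] - mapx[il, j]) / (ir - il)
    dyy <- (mapy[ir, j] - mapy[il, j]) / (ir - il)
    out[i, j] <- dxx * dyy - dxy * dyx
  }
  out
}

# small trained-free model bundle for plumbing tests
tiny_models <- function(L = 4L, seed = 1) {
  set.seed(seed)
  rc <- regnet_config(L, kernel1 = 15L, kernel2 = 7L, base_channels = 4L)
  list(unet = build_feature_net(L, 4L),
       net1 = build_regnet(rc, 1L),
       net2 = build_regnet(rc, 2L))
}
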