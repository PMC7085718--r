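# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A tape records nodes in creation order; each non-leaf node keeps a closure
# mapping the incoming gradient to the gradients of its parents. backward()
# walks the tape in reverse, accumulating into $grad. Values are plain R
# arrays (H, W, C) or scalars; the heavy ops call the C++ kernels.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$k]] <- n
  n$id <- tape$k
  n
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_backward <- function(tape, root) {
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  for (i in rev(seq_len(tape$k))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      if (is.null(gs[[j]])) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

# ---- ops ------------------------------------------------------------------

ad_conv <- function(tape, x, w, b, kh, kw, stride, pad, need_gx = TRUE) {
  fw <- .cpp_conv2d_fw_col(x$value, w$value, b$value, kh, kw, stride, pad)
  d <- dim(x$value); wv <- w$value; col <- fw$col
  ad_node(tape, fw$y, list(x, w, b), function(g) {
    r <- .cpp_conv2d_bw_cached(col, wv, g, d[1], d[2], d[3], kh, kw,
                               stride, pad, need_gx)
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

ad_leaky_relu <- function(tape, x, alpha = 0.1) {
  xv <- x$value
  v <- ifelse(xv > 0, xv, alpha * xv)
  ad_node(tape, v, list(x), function(g) list(g * ifelse(xv > 0, 1, alpha)))
}

# channel softmax over the 3rd dimension of (H, W, L)
ad_softmax <- function(tape, x) {
  d <- dim(x$value)
  m <- matrix(x$value, nrow = d[1] * d[2], ncol = d[3])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  pv <- array(p, d)
  ad_node(tape, pv, list(x), function(g) {
    gm <- matrix(g, nrow = d[1] * d[2], ncol = d[3])
    dot <- rowSums(gm * p)
    list(array(p * (gm - dot), d))
  })
}

ad_concat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ad_node(tape, v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ad_avgpool <- function(tape, x, k) {
  ad_node(tape, .cpp_avgpool_fw(x$value, k), list(x),
          function(g) list(.cpp_avgpool_bw(g, k)))
}

ad_upsample_nearest <- function(tape, x, f) {
  ad_node(tape, .cpp_upsample_nearest_fw(x$value, f), list(x),
          function(g) list(.cpp_upsample_nearest_bw(g, f)))
}

ad_crop <- function(tape, x, oi, oj, H, W) {
  d <- dim(x$value)
  v <- x$value[oi + seq_len(H), oj + seq_len(W), , drop = FALSE]
  ad_node(tape, v, list(x), function(g) {
    gx <- array(0, d)
    gx[oi + seq_len(H), oj + seq_len(W), ] <- g
    list(gx)
  })
}

ad_resize_bilinear <- function(tape, x, Ho, Wo) {
  d <- dim(x$value)
  ad_node(tape, .cpp_resize_bilinear_fw(x$value, Ho, Wo), list(x),
          function(g) list(.cpp_resize_bilinear_bw(g, d[1], d[2])))
}

ad_scale <- function(tape, x, a) {
  ad_node(tape, x$value * a, list(x), function(g) list(g * a))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# backward bilinear warp; gradients flow to both source and field
ad_warp <- function(tape, src, field) {
  sv <- src$value; fv <- field$value
  ad_node(tape, .cpp_warp_bilinear_fw(sv, fv), list(src, field), function(g) {
    r <- .cpp_warp_bilinear_bw(sv, fv, g)
    list(r$gsrc, r$gfield)
  })
}

ad_compose <- function(tape, v_outer, v_inner, mode) {
  if (mode == "additive") ad_add(tape, v_inner, v_outer)
  else ad_add(tape, v_outer, ad_warp(tape, v_inner, v_outer))
}

ad_scaling_and_squaring <- function(tape, vel, steps) {
  fld <- ad_scale(tape, vel, 1 / 2^steps)
  for (s in seq_len(steps)) fld <- ad_compose(tape, fld, fld, "transform")
  fld
}

# weighted cross-entropy of channel probabilities vs an integer label grid
ad_weighted_ce <- function(tape, probs, truth, w, eps = 1e-7) {
  d <- dim(probs$value)
  N <- d[1] * d[2]
  pm <- matrix(probs$value, nrow = N, ncol = d[3])
  idx <- cbind(seq_len(N), as.integer(truth) + 1L)
  pt <- pmax(pm[idx], eps)
  wt <- w[as.integer(truth) + 1L]
  v <- -sum(wt * log(pt)) / N
  ad_node(tape, v, list(probs), function(g) {
    gm <- matrix(0, nrow = N, ncol = d[3])
    gm[idx] <- ifelse(pm[idx] >= eps, -g * wt / (N * pt), 0)
    list(array(gm, d))
  })
}

# (1/L) sum_l w_l * mean |target_l - x_l| ; target is a constant array
ad_weighted_l1 <- function(tape, target, x, w) {
  d <- dim(x$value)
  N <- d[1] * d[2]; L <- d[3]
  diffs <- target - x$value
  wl <- array(rep(w, each = N), d)
  v <- sum(wl * abs(diffs)) / (L * N)
  ad_node(tape, v, list(x), function(g) {
    list(g * wl * -sign(diffs) / (L * N))
  })
}

ad_mean_sq <- function(tape, x) {
  n <- length(x$value)
  xv <- x$value
  ad_node(tape, sum(xv^2) / n, list(x), function(g) list(g * 2 * xv / n))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

# weighted sum of scalar nodes: sum_i coefs[i] * nodes[[i]]
ad_axpy <- function(tape, coefs, nodes) {
  v <- sum(coefs * vapply(nodes, function(n) n$value, numeric(1)))
  ad_node(tape, v, nodes, function(g) as.list(g * coefs))
}
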