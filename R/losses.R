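# Training objective: weighted cross-entropy on the semantic features,
# label-alignment (deformation) loss on warped one-hot segmentations, and a
# smoothness penalty tying the field to a locally averaged version of itself.

#' Square-root inverse-frequency class weights
#'
#' `w_l = sqrt(total_pixels / count_l)`, normalized to mean 1 so that the
#' semantic loss weight keeps its meaning across label sets. Counts are
#' pooled over all supplied label maps.
#'
#' @param labels a label matrix or list of label matrices (values in
#'   `0 .. num_labels - 1`).
#' @param num_labels L.
#' @param floor_count minimum count substituted for absent labels; the
#'   default 0 makes an absent label an error.
#' @return numeric vector of length L with mean 1.
#' @export
class_weights <- function(labels, num_labels, floor_count = 0L) {
  if (!is.list(labels)) labels <- list(labels)
  counts <- numeric(num_labels)
  for (lab in labels) {
    if (any(lab >= num_labels | lab < 0)) stop("label id outside 0..L-1")
    tab <- tabulate(as.integer(lab) + 1L, nbins = num_labels)
    counts <- counts + tab
  }
  if (any(counts == 0)) {
    if (floor_count <= 0)
      stop("label(s) ", paste(which(counts == 0) - 1L, collapse = ", "),
           " never occur; supply floor_count to proceed")
    counts <- pmax(counts, floor_count)
  }
  w <- sqrt(sum(counts) / counts)
  w / mean(w)
}

#' Weighted cross-entropy semantic loss
#'
#' Mean over feature-grid pixels of `-w[truth] * log(probs[truth])`, with
#' probabilities clipped at `eps = 1e-7` before the logarithm.
#'
#' @param probs `(h, w, L)` softmax probabilities.
#' @param truth `(h, w)` integer label matrix at the same (feature)
#'   resolution.
#' @param w length-L class weights (see [class_weights()]).
#' @return non-negative scalar.
#' @export
semantic_loss <- function(probs, truth, w, eps = 1e-7) {
  d <- dim(probs)
  if (!all(dim(truth) == d[1:2]) || length(w) != d[3])
    stop("shape mismatch between probs, truth and weights")
  tape <- ad_tape()
  ad_weighted_ce(tape, ad_leaf(tape, probs), truth, w, eps)$value
}

#' One-hot encode a label map
#'
#' @param labels `(H, W)` integer matrix with values in `0 .. L-1`.
#' @param num_labels L.
#' @return `(H, W, L)` array of 0/1 channels.
#' @export
one_hot <- function(labels, num_labels) {
  if (any(labels >= num_labels | labels < 0)) stop("label id outside 0..L-1")
  d <- dim(labels)
  out <- array(0, c(d, num_labels))
  for (l in seq_len(num_labels))
    out[, , l] <- (labels == l - 1L) + 0
  out
}

#' Label-alignment (deformation) loss
#'
#' Both label maps are one-hot encoded, the moving channels are warped
#' bilinearly by the field, and the loss is the class-weighted mean absolute
#' difference: `(1/L) sum_l w_l * mean |Sf_l - T(V, Sm_l)|`.
#'
#' @param fixed_labels,moving_labels `(H, W)` integer label matrices.
#' @param field `(H, W, 2)` displacement field on the fixed grid.
#' @param w length-L label weights.
#' @return non-negative scalar, bounded by `max(w)`.
#' @export
deformation_loss <- function(fixed_labels, moving_labels, field, w) {
  L <- length(w)
  sf <- one_hot(fixed_labels, L)
  sm <- one_hot(moving_labels, L)
  check_field(field)
  if (!all(dim(field)[1:2] == dim(fixed_labels))) stop("shape mismatch")
  tape <- ad_tape()
  warped <- ad_warp(tape, ad_leaf(tape, sm), ad_leaf(tape, field))
  ad_weighted_l1(tape, sf, warped, w)$value
}

#' Smoothness (regularization) loss
#'
#' Mean squared difference between the field and a locally smoothed version
#' of itself, `Vsmooth = smooth_field(V, kernel, passes)`. Zero for constant
#' fields, and for affine fields away from the borders.
#'
#' @param field `(H, W, 2)` field.
#' @param kernel odd average-pooling size (default 3).
#' @param passes pooling passes (default 2).
#' @return non-negative scalar.
#' @export
regularization_loss <- function(field, kernel = 3L, passes = 2L) {
  vs <- smooth_field(field, kernel, passes)
  mean((field - vs)^2)
}

#' Loss weights for the total training objective
#'
#' @param lambda_s semantic loss weight (default 1.0).
#' @param lambda_r regularization weight (default 0.001).
#' @param label_weights length-L class weights used by the semantic and
#'   deformation losses.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_s = 1.0, lambda_r = 0.001,
                         label_weights = NULL) {
  if (lambda_s < 0 || lambda_r < 0) stop("loss weights must be non-negative")
  structure(list(lambda_s = lambda_s, lambda_r = lambda_r,
                 label_weights = label_weights), class = "loss_weights")
}

#' Total training loss
#'
#' `lambda_s * (L_semantic_fixed + L_semantic_moving) + L_deform +
#'  lambda_r * L_regular`.
#'
#' @param semantic_f,semantic_m semantic losses of the fixed and moving
#'   image predictions.
#' @param deform deformation loss.
#' @param regular regularization loss.
#' @param lw a [loss_weights()].
#' @return scalar; non-finite inputs raise an error.
#' @export
total_loss <- function(semantic_f, semantic_m, deform, regular, lw) {
  terms <- c(semantic_f, semantic_m, deform, regular)
  if (!all(is.finite(terms)))
    stop("non-finite loss term: ",
         paste(c("semantic_f", "semantic_m", "deform", "regular")[!is.finite(terms)],
               collapse = ", "))
  lw$lambda_s * (semantic_f + semantic_m) + deform + lw$lambda_r * regular
}
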