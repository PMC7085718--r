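# Two-step registration cascade: step 1 predicts a coarse B-spline field V1
# from the concatenated semantic features, the moving features are warped by
# V1, step 2 predicts a refinement V2 from the warped pair, and the two
# fields are combined into the final field V. Fields are predicted and
# composed at feature (half) resolution, then bilinearly rescaled x2 (values
# doubled) to image resolution.

# tape-level cascade; returns field nodes. models: list(net1, net2 or NULL)
cascade_forward <- function(tape, models, pn1, pn2, ffn, fmn,
                            combine_mode = "transform", diffeo = FALSE,
                            ss_steps = 6L) {
  v1 <- regnet_field(tape, models$net1, pn1, ffn, fmn, diffeo, ss_steps)
  if (is.null(models$net2))
    return(list(v1 = v1, v2 = NULL, v = v1))
  fmw <- ad_warp(tape, fmn, v1)
  v2 <- regnet_field(tape, models$net2, pn2, ffn, fmw, diffeo, ss_steps)
  mode <- if (diffeo) "transform" else combine_mode
  list(v1 = v1, v2 = v2, v = ad_compose(tape, v2, v1, mode))
}

upscale_field_node <- function(tape, v) {
  d <- dim(v$value)
  ad_scale(tape, ad_resize_bilinear(tape, v, 2L * d[1], 2L * d[2]), 2)
}

#' Rescale a displacement field to a larger grid
#'
#' Bilinear resampling with the displacement values multiplied by the scale
#' factor, so the field keeps its meaning in pixels of the new grid.
#'
#' @param field `(h, w, 2)` field.
#' @param factor integer upscale factor (default 2).
#' @return `(h * factor, w * factor, 2)` field.
#' @export
upscale_field <- function(field, factor = 2L) {
  check_field(field)
  d <- dim(field)
  .cpp_resize_bilinear_fw(field, d[1] * factor, d[2] * factor) * factor
}

finish_result <- function(v1h, v2h, vh, moving_image = NULL,
                          moving_labels = NULL) {
  res <- list(
    v1 = upscale_field(v1h),
    v2 = if (is.null(v2h)) NULL else upscale_field(v2h),
    v  = upscale_field(vh)
  )
  if (!is.null(moving_image))
    res$warped_moving <- warp_image(moving_image, res$v, "bilinear")
  if (!is.null(moving_labels))
    res$warped_moving_labels <- warp_image(moving_labels, res$v, "nearest")
  structure(res, class = "registration_result")
}

#' Two-step registration from semantic features
#'
#' @param ff,fm `(h, w, L)` feature maps (softmax probabilities) of the fixed
#'   and moving image at half image resolution.
#' @param net1,net2 networks from [build_regnet()] (steps 1 and 2). Passing
#'   the same object for both shares the cascade weights.
#' @param combine_mode how V2 and V1 are combined: `"transform"` gives
#'   `V(x) = V2(x) + V1(x + V2(x))` (warp by V equals warping by V1 then V2);
#'   `"additive"` gives `V = V1 + V2`.
#' @param diffeomorphic if `TRUE` the network outputs are read as stationary
#'   velocity fields and exponentiated by [scaling_and_squaring()]; the
#'   combine mode is then forced to `"transform"`.
#' @param moving_image,moving_labels optional full-resolution grids to warp
#'   with the final field.
#' @return a `registration_result`: fields `v1`, `v2`, `v` at full image
#'   resolution (pixel units) plus any warped outputs.
#' @export
two_step_register <- function(ff, fm, net1, net2,
                              combine_mode = c("transform", "additive"),
                              diffeomorphic = FALSE,
                              moving_image = NULL, moving_labels = NULL) {
  combine_mode <- match.arg(combine_mode)
  if (!all(dim(ff) == dim(fm))) stop("feature map shapes differ")
  shared <- identical(net1, net2)
  tape <- ad_tape()
  pn1 <- param_nodes(tape, net1$params)
  pn2 <- if (shared) pn1 else param_nodes(tape, net2$params)
  out <- cascade_forward(tape, list(net1 = net1, net2 = net2), pn1, pn2,
                         ad_leaf(tape, ff), ad_leaf(tape, fm),
                         combine_mode, diffeomorphic)
  finish_result(out$v1$value, out$v2$value, out$v$value,
                moving_image, moving_labels)
}

#' Single-step registration from semantic features
#'
#' One registration network of the full parameter budget predicts the field
#' in a single step (the single-step ablation).
#'
#' @inheritParams two_step_register
#' @param net a network from [build_regnet()].
#' @return a `registration_result` with `v = v1` and `v2 = NULL`.
#' @export
single_step_register <- function(ff, fm, net, diffeomorphic = FALSE,
                                 moving_image = NULL, moving_labels = NULL) {
  if (!all(dim(ff) == dim(fm))) stop("feature map shapes differ")
  tape <- ad_tape()
  pn <- param_nodes(tape, net$params)
  out <- cascade_forward(tape, list(net1 = net, net2 = NULL), pn, NULL,
                         ad_leaf(tape, ff), ad_leaf(tape, fm),
                         diffeo = diffeomorphic)
  finish_result(out$v1$value, NULL, out$v$value, moving_image, moving_labels)
}
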