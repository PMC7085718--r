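# Geometric machinery: B-spline densification, warping, smoothing, field
# composition, scaling-and-squaring, Jacobian determinants.
#
# Conventions (fixed throughout the package):
#   * grids are R arrays, dim (H, W) or (H, W, C), column-major;
#   * a displacement field is an (H, W, 2) array, slice 1 = Dx (columns),
#     slice 2 = Dy (rows), in pixels of the grid it lives on;
#   * warping is backward (pull): output(x) = source(x + D(x)), x = (col, row),
#     0-based in the maths, with out-of-bounds samples clamped to the border.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

check_field <- function(field, what = "field") {
  if (!(is.array(field) && length(dim(field)) == 3L && dim(field)[3] == 2L))
    stop(what, " must be an (H, W, 2) array")
  if (!all(is.finite(field))) stop(what, " contains non-finite values")
  invisible(field)
}

check_odd_kernel <- function(kernel) {
  if (length(kernel) != 1L || kernel < 1L || kernel %% 2L != 1L)
    stop("kernel must be a positive odd integer, got ", kernel)
  as.integer(kernel)
}

#' Construct a B-spline control grid
#'
#' A low-parametric representation of a deformation: a coarse grid of
#' 2D displacement vectors (in pixels of the full-resolution image) with a
#' fixed spacing between control points. Densified to a per-pixel field by
#' [densify()].
#'
#' @param values numeric array of dim `(h', w', 2)`; slice 1 is the
#'   x-displacement (columns), slice 2 the y-displacement (rows).
#' @param spacing integer number of image pixels between control points.
#' @return an object of class `control_grid`.
#' @export
control_grid <- function(values, spacing) {
  check_field(values, "control grid values")
  if (dim(values)[1] < 2L || dim(values)[2] < 2L)
    stop("control grid must be at least 2 x 2")
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop("spacing must be >= 1")
  structure(list(values = values, spacing = spacing), class = "control_grid")
}

#' Densify a control grid to a per-pixel displacement field
#'
#' Realizes cubic B-spline interpolation of the control-point displacements
#' through the recursive cardinal-spline construction: the control grid is
#' upsampled by nearest-neighbour replication (factor = spacing), centre-
#' cropped to the target shape, and smoothed by three consecutive unit-stride
#' average-pooling passes of size `kernel x kernel` with replicate padding.
#' The operation is linear in the control values and maps constant grids to
#' constant fields (partition of unity).
#'
#' @param control a [control_grid()].
#' @param target_shape integer `c(H, W)` of the full-resolution field.
#' @param kernel odd pooling size; the default `2 * spacing - 1` gives
#'   overlapping cubic supports matched to the control spacing.
#' @return an `(H, W, 2)` displacement field.
#' @export
densify <- function(control, target_shape,
                    kernel = 2L * control$spacing - 1L) {
  stopifnot(inherits(control, "control_grid"))
  kernel <- check_odd_kernel(kernel)
  H <- as.integer(target_shape[1]); W <- as.integer(target_shape[2])
  s <- control$spacing
  d <- dim(control$values)
  if (d[1] != ceiling(H / s) || d[2] != ceiling(W / s))
    stop("control grid (", d[1], "x", d[2], ") inconsistent with target ",
         H, "x", W, " at spacing ", s)
  if (kernel > H || kernel > W)
    stop("kernel (", kernel, ") larger than target grid dimension")
  up <- .cpp_upsample_nearest_fw(control$values, s)
  oi <- (dim(up)[1] - H) %/% 2L
  oj <- (dim(up)[2] - W) %/% 2L
  fld <- up[oi + seq_len(H), oj + seq_len(W), , drop = FALSE]
  for (p in 1:3) fld <- .cpp_avgpool_fw(fld, kernel)
  fld
}

#' Backward-warp an image, label map, or multi-channel grid
#'
#' `output(x) = source(x + D(x))`: the field lives on the output (fixed) grid
#' and gives, per pixel, the displacement to the sampling location in the
#' source. Out-of-bounds samples replicate the border.
#'
#' @param source `(H, W)` matrix or `(H, W, C)` array.
#' @param field `(H, W, 2)` displacement field in pixels.
#' @param mode `"bilinear"` for intensities/probabilities/one-hot channels,
#'   `"nearest"` for integer label maps.
#' @return warped grid with the shape of `source`.
#' @export
warp_image <- function(source, field, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  check_field(field)
  src <- as_cube(source)
  if (!all(dim(src)[1:2] == dim(field)[1:2]))
    stop("source (", paste(dim(src)[1:2], collapse = "x"),
         ") and field (", paste(dim(field)[1:2], collapse = "x"),
         ") shapes differ")
  out <- if (mode == "bilinear") .cpp_warp_bilinear_fw(src, field)
         else .cpp_warp_nearest(src, field)
  if (is.matrix(source)) out <- out[, , 1L]
  if (is.matrix(source) && mode == "nearest" && is.integer(source))
    storage.mode(out) <- "integer"
  out
}

#' Smooth a displacement field by repeated average pooling
#'
#' @param field `(H, W, 2)` field.
#' @param kernel odd pooling size.
#' @param passes number of unit-stride pooling passes (replicate padding).
#' @return smoothed field, same shape.
#' @export
smooth_field <- function(field, kernel, passes = 2L) {
  check_field(field)
  kernel <- check_odd_kernel(kernel)
  passes <- as.integer(passes)
  if (passes < 1L) stop("passes must be >= 1")
  for (p in seq_len(passes)) field <- .cpp_avgpool_fw(field, kernel)
  field
}

#' Compose two displacement fields
#'
#' With `v_outer` the second (refinement) field and `v_inner` the first,
#' `"additive"` returns `V(x) = v_inner(x) + v_outer(x)` and `"transform"`
#' returns `V(x) = v_outer(x) + v_inner(x + v_outer(x))` (bilinear sampling
#' of `v_inner`), so that warping once by `V` equals warping by `v_inner`
#' and then by `v_outer`.
#'
#' @param v_outer,v_inner `(H, W, 2)` fields.
#' @param mode `"additive"` or `"transform"`.
#' @return combined `(H, W, 2)` field.
#' @export
compose_fields <- function(v_outer, v_inner, mode = c("additive", "transform")) {
  mode <- match.arg(mode)
  check_field(v_outer); check_field(v_inner)
  if (!all(dim(v_outer) == dim(v_inner))) stop("field shapes differ")
  if (mode == "additive") v_inner + v_outer
  else v_outer + .cpp_warp_bilinear_fw(v_inner, v_outer)
}

#' Exponentiate a stationary velocity field by scaling and squaring
#'
#' Divides the velocity by `2^steps` and composes the small field with itself
#' `steps` times (transform mode). For moderate velocities the result is a
#' diffeomorphic displacement field (positive Jacobian determinants in the
#' interior).
#'
#' @param velocity `(H, W, 2)` stationary velocity field in pixels.
#' @param steps number of squaring steps (default 6).
#' @return `(H, W, 2)` displacement field.
#' @export
scaling_and_squaring <- function(velocity, steps = 6L) {
  check_field(velocity, "velocity")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  fld <- velocity / 2^steps
  for (s in seq_len(steps)) fld <- compose_fields(fld, fld, "transform")
  fld
}

#' Per-pixel Jacobian determinant of a deformation
#'
#' Determinant of `I + grad(D)` for the mapping `x -> x + D(x)`, using central
#' finite differences (spacing 1 px) in the interior and one-sided differences
#' at the borders. The identity field yields 1 everywhere; values <= 0 flag
#' folding/singularities.
#'
#' @param field `(H, W, 2)` displacement field.
#' @return `(H, W)` matrix of determinants.
#' @export
jacobian_determinant <- function(field) {
  check_field(field)
  ddx <- function(m) { # derivative along x = columns
    W <- ncol(m)
    g <- m
    if (W >= 3L) g[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
    g[, 1] <- m[, 2] - m[, 1]
    g[, W] <- m[, W] - m[, W - 1]
    g
  }
  ddy <- function(m) t(ddx(t(m)))
  dxdx <- ddx(field[, , 1]); dxdy <- ddy(field[, , 1])
  dydx <- ddx(field[, , 2]); dydy <- ddy(field[, , 2])
  (1 + dxdx) * (1 + dydy) - dxdy * dydx
}

#' Write / read a displacement field
#'
#' Fields are stored as 2-channel 32-bit float NIfTI (`.nii`/`.nii.gz`,
#' channels along the 4th dimension, requires the RNifti package) or as an R
#' serialization (`.rds`). A sidecar `.txt` header records the unit and axis
#' convention.
#'
#' @param field `(H, W, 2)` field.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  check_field(field)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI output requires the RNifti package")
    arr <- array(field, dim = c(dim(field)[1:2], 1L, 2L))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  } else if (grepl("\\.rds$", path)) {
    saveRDS(field, path)
  } else stop("unsupported field extension: ", path)
  writeLines(c("displacement field, pixel units",
               "channel 1 = Dx (columns), channel 2 = Dy (rows)",
               "backward convention: output(x) = source(x + D(x))",
               "x = column, y = row, origin top-left, 0-based"),
             paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    arr <- as.array(RNifti::readNifti(path))
    field <- array(arr, dim = c(dim(arr)[1:2], 2L))
  } else if (grepl("\\.rds$", path)) {
    field <- readRDS(path)
  } else stop("unsupported field extension: ", path)
  check_field(field)
  field
}
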