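# Synthetic scenes with known ground-truth B-spline deformations. Two
# regimes: "cardiac" (a ventricle-like ring anatomy: blood pool, myocardial
# ring, and an adjacent second chamber; L = 4) and "face" (a face-part-like
# layout of nested/adjacent ellipses; L = 8). The generating deformations
# are drawn from the same B-spline family the model predicts (control grid +
# triple average pooling), so exact recovery is representable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic scene family
#'
#' Defines the image geometry, label set, intensity model and deformation
#' model from which [generate_pair()] draws. Structure sizes scale with the
#' image so the same spec works at reduced resolutions. All shapes keep a
#' margin of at least `max_displacement + 2` pixels from the border so
#' deformed structures stay in bounds.
#'
#' @param image_size `c(H, W)`, both divisible by 8 (default 64 x 64).
#' @param scene_type `"cardiac"` (L = 4: background, second chamber,
#'   myocardial ring, blood pool) or `"face"` (L = 8: background, head,
#'   two brows, two eyes, nose, mouth).
#' @param control_spacing control-point spacing of the generating B-spline
#'   deformation, in image pixels (default 8).
#' @param max_displacement target maximum displacement magnitude in pixels
#'   (default 10; large relative to the ~12 px structures).
#' @param displacement_sd standard deviation of the raw control-point
#'   displacements; the default `1.1 * max_displacement` is calibrated so
#'   the densified field's maximum magnitude lands near the target (pooling
#'   attenuates the control-point amplitudes).
#' @param noise_sd additive Gaussian intensity noise (default 0.02).
#' @param contrast_jitter range of per-structure multiplicative contrast
#'   applied independently to the two images of a pair (default 0.7..1.3).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(64L, 64L),
                       scene_type = c("cardiac", "face"),
                       control_spacing = 8L,
                       max_displacement = 10,
                       displacement_sd = 1.1 * max_displacement,
                       noise_sd = 0.02,
                       contrast_jitter = c(0.7, 1.3)) {
  scene_type <- match.arg(scene_type)
  image_size <- as.integer(image_size)
  if (any(image_size %% 8L != 0L)) stop("image size must be divisible by 8")
  num_labels <- if (scene_type == "cardiac") 4L else 8L
  margin <- max_displacement + 2
  if (min(image_size) / 2 - margin < 8 * min(image_size) / 64)
    stop("shapes cannot fit with margin >= max_displacement")
  structure(list(image_size = image_size, scene_type = scene_type,
                 num_labels = num_labels,
                 control_spacing = as.integer(control_spacing),
                 max_displacement = max_displacement,
                 displacement_sd = displacement_sd,
                 noise_sd = noise_sd, contrast_jitter = contrast_jitter,
                 margin = margin),
            class = "scene_spec")
}

# paint an axis-aligned ellipse into a label matrix
paint_ellipse <- function(lab, cy, cx, ry, rx, value) {
  H <- nrow(lab); W <- ncol(lab)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  lab[inside] <- value
  lab
}

sample_geometry <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  avail <- min(H, W) / 2 - spec$margin
  # structure sizes scale with the image, shrinking further when a large
  # deformation budget eats into the available radius (20 units is the
  # default-geometry extent that placement retries can accommodate)
  sc <- min(H, W) / 64
  sc <- sc * min(1, avail / (20 * sc))
  for (try in 1:50) {
    lab <- matrix(0L, H, W)
    cy <- H / 2 + runif(1, -2, 2) * sc
    cx <- W / 2 + runif(1, -2, 2) * sc
    if (spec$scene_type == "cardiac") {
      r_lv <- runif(1, 4.5, 6.5) * sc
      thick <- runif(1, 2.5, 4) * sc
      r_out <- r_lv + thick
      rv_a <- runif(1, 5, 7.5) * sc   # x semi-axis
      rv_b <- runif(1, 3.5, 5.5) * sc # y semi-axis
      rv_cx <- cx - (r_out + 0.55 * rv_a)
      rv_cy <- cy + runif(1, -2, 2) * sc
      extent <- max(r_out, abs(rv_cx - cx) + rv_a, abs(rv_cy - cy) + rv_b)
      if (extent > avail) next
      lab <- paint_ellipse(lab, rv_cy, rv_cx, rv_b, rv_a, 1L)
      lab <- paint_ellipse(lab, cy, cx, r_out, r_out, 2L)
      lab <- paint_ellipse(lab, cy, cx, r_lv, r_lv, 3L)
    } else {
      fy <- runif(1, 16, 19) * sc; fx <- runif(1, 12, 15) * sc
      if (max(fy, fx) > avail) next
      lab <- paint_ellipse(lab, cy, cx, fy, fx, 1L)
      ey <- cy - 0.35 * fy; ex <- 0.5 * fx
      lab <- paint_ellipse(lab, ey - 0.25 * fy, cx - ex, 1.2 * sc, 2.6 * sc, 2L) # brows
      lab <- paint_ellipse(lab, ey - 0.25 * fy, cx + ex, 1.2 * sc, 2.6 * sc, 3L)
      lab <- paint_ellipse(lab, ey, cx - ex, 1.8 * sc, 2.2 * sc, 4L)             # eyes
      lab <- paint_ellipse(lab, ey, cx + ex, 1.8 * sc, 2.2 * sc, 5L)
      lab <- paint_ellipse(lab, cy + 0.1 * fy, cx, 3.2 * sc, 1.7 * sc, 6L)       # nose
      lab <- paint_ellipse(lab, cy + 0.55 * fy, cx, 1.9 * sc, 4.2 * sc, 7L)      # mouth
    }
    if (length(unique(as.integer(lab))) == spec$num_labels) return(lab)
  }
  stop("could not place structures after 50 attempts")
}

base_intensities <- function(spec) {
  if (spec$scene_type == "cardiac") c(0.15, 0.75, 0.35, 0.90)
  else c(0.10, 0.60, 0.25, 0.25, 0.90, 0.90, 0.45, 0.30)
}

render_scene <- function(labels, spec) {
  mu <- base_intensities(spec)
  jit <- runif(spec$num_labels, spec$contrast_jitter[1], spec$contrast_jitter[2])
  img <- matrix(mu[labels + 1L] * jit[labels + 1L], nrow(labels), ncol(labels))
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = spec$noise_sd),
                        nrow(labels), ncol(labels))
  pmin(pmax(img, 0), 1)
}

#' Rasterize a random scene template
#'
#' Samples structure positions/sizes within the spec's ranges and renders an
#' intensity image with per-structure contrast jitter and additive noise.
#' Deterministic for a fixed seed.
#'
#' @param spec a [scene_spec()].
#' @param rng_seed integer seed.
#' @return list with `image` (`(H, W)` matrix in `[0, 1]`) and `labels`
#'   (`(H, W)` integer matrix).
#' @export
make_template <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(rng_seed, {
    labels <- sample_geometry(spec)
    list(image = render_scene(labels, spec), labels = labels)
  })
}

#' Sample a smooth random B-spline deformation
#'
#' Control-point displacements are drawn i.i.d. Normal(0, sd^2), clipped to
#' the target magnitude, and densified with [densify()]. The dense field is
#' rescaled down if its maximum magnitude exceeds the target (a linear
#' operation, staying inside the B-spline family), and resampled (bounded
#' retries) until all Jacobian determinants are strictly positive.
#'
#' @param spec a [scene_spec()].
#' @param rng_seed integer seed.
#' @return an `(H, W, 2)` displacement field (fixed-to-moving, backward
#'   convention).
#' @export
sample_deformation <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  s <- spec$control_spacing
  kernel <- 2L * s - 1L
  with_seed(rng_seed, {
    if (spec$displacement_sd == 0) return(array(0, c(H, W, 2L)))
    for (try in 1:25) {
      vals <- array(rnorm(ceiling(H / s) * ceiling(W / s) * 2,
                          sd = spec$displacement_sd),
                    c(ceiling(H / s), ceiling(W / s), 2L))
      vals <- pmin(pmax(vals, -spec$max_displacement), spec$max_displacement)
      fld <- densify(control_grid(vals, s), c(H, W), kernel)
      mx <- max(sqrt(fld[, , 1]^2 + fld[, , 2]^2))
      if (mx > spec$max_displacement)
        fld <- fld * (spec$max_displacement / mx)
      if (jacobian_summary(fld)$negative_fraction == 0) return(fld)
    }
    stop("could not sample a fold-free deformation after 25 attempts")
  })
}

#' Generate one synthetic image pair with known deformation
#'
#' The template becomes the moving image; the fixed image is obtained by
#' warping the template geometry with the sampled field, so that
#' `fixed = warp(moving, true_field)` holds exactly (backward convention:
#' `true_field` lives on the fixed grid). Intensities are rendered
#' independently for the two images (independent contrast jitter and noise),
#' emulating inter-subject appearance variation.
#'
#' @param spec a [scene_spec()].
#' @param rng_seed integer seed; output is deterministic per seed.
#' @return a `synthetic_pair`: `fixed`, `moving` (images), `fixed_labels`,
#'   `moving_labels`, `true_field`, `magnitude` (max displacement norm),
#'   `seed`.
#' @export
generate_pair <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "scene_spec"))
  seeds <- with_seed(rng_seed, sample.int(2^31 - 1, 4))
  moving_labels <- with_seed(seeds[1], sample_geometry(spec))
  true_field <- sample_deformation(spec, seeds[2])
  fixed_labels <- warp_image(moving_labels, true_field, "nearest")
  moving <- with_seed(seeds[3], render_scene(moving_labels, spec))
  fixed <- with_seed(seeds[4], render_scene(fixed_labels, spec))
  structure(list(fixed = fixed, moving = moving,
                 fixed_labels = fixed_labels, moving_labels = moving_labels,
                 true_field = true_field,
                 magnitude = max(sqrt(true_field[, , 1]^2 + true_field[, , 2]^2)),
                 seed = rng_seed),
            class = "synthetic_pair")
}

#' Write a synthetic dataset to disk with a manifest
#'
#' Images and label maps are written as PNG, ground-truth fields as `.rds`
#' (or NIfTI when RNifti is available and `field_format = "nii.gz"`). The
#' manifest CSV records per pair: id, seed, train/test split, deformation
#' magnitude, and all file paths (relative to `out_dir`).
#'
#' @param spec a [scene_spec()].
#' @param n_pairs number of pairs (>= 1).
#' @param base_seed integer; pair i uses seed `base_seed + i - 1`.
#' @param out_dir output directory.
#' @param train_fraction fraction of pairs labelled `train` (default 0.7).
#' @param overwrite allow writing into an existing non-empty directory.
#' @param field_format `"rds"` or `"nii.gz"`.
#' @return the manifest data frame, invisibly; written to
#'   `<out_dir>/manifest.csv`.
#' @export
make_dataset <- function(spec, n_pairs, base_seed, out_dir,
                         train_fraction = 0.7, overwrite = FALSE,
                         field_format = c("rds", "nii.gz")) {
  stopifnot(inherits(spec, "scene_spec"), n_pairs >= 1)
  field_format <- match.arg(field_format)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_train <- round(train_fraction * n_pairs)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pair <- generate_pair(spec, base_seed + i - 1L)
    id <- sprintf("pair_%04d", i)
    paths <- c(fixed = paste0(id, "_fixed.png"),
               moving = paste0(id, "_moving.png"),
               fixed_labels = paste0(id, "_fixed_labels.png"),
               moving_labels = paste0(id, "_moving_labels.png"),
               field = paste0(id, "_field.", field_format))
    write_image(pair$fixed, file.path(out_dir, paths["fixed"]))
    write_image(pair$moving, file.path(out_dir, paths["moving"]))
    write_labels(pair$fixed_labels, file.path(out_dir, paths["fixed_labels"]))
    write_labels(pair$moving_labels, file.path(out_dir, paths["moving_labels"]))
    write_field(pair$true_field, file.path(out_dir, paths["field"]))
    rows[[i]] <- data.frame(pair_id = id, seed = base_seed + i - 1L,
                            split = if (i <= n_train) "train" else "test",
                            magnitude = pair$magnitude,
                            t(paths), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset pair referenced by a manifest row
#'
#' @param row one row of a manifest from [make_dataset()].
#' @param dir the dataset directory.
#' @return a `synthetic_pair` (without renderer metadata).
#' @export
load_pair <- function(row, dir) {
  structure(list(
    fixed = read_image(file.path(dir, row$fixed)),
    moving = read_image(file.path(dir, row$moving)),
    fixed_labels = read_labels(file.path(dir, row$fixed_labels)),
    moving_labels = read_labels(file.path(dir, row$moving_labels)),
    true_field = read_field(file.path(dir, row$field)),
    magnitude = row$magnitude, seed = row$seed
  ), class = "synthetic_pair")
}
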