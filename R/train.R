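# End-to-end training of the U-Net + registration cascade, inference from a
# checkpoint, and dataset-level evaluation.

#' Training configuration
#'
#' Defaults follow the published recipe where one exists: Adam with learning
#' rate 0.001 and first-moment decay 0.97, semantic weight `lambda_s = 1.0`,
#' regularization weight `lambda_r = 0.001`, batch size 5. The B-spline
#' pooling kernels default to 15 and 7 (suited to 64 px synthetic images;
#' the 320 px face-scale counterparts are 19 and 11, the 128 px cardiac ones
#' 5 and 3), with field smoothing kernel 3 over two passes.
#'
#' @param epochs training epochs.
#' @param batch_size pairs per optimizer step.
#' @param lr,beta1 Adam learning rate and first-moment decay.
#' @param lambda_s,lambda_r semantic and regularization loss weights.
#' @param kernel1,kernel2 B-spline pooling kernels of cascade steps 1 and 2.
#' @param smooth_kernel,smooth_passes field smoothing used by the
#'   regularization loss.
#' @param combine_mode `"transform"` or `"additive"` field combination.
#' @param two_step cascade (TRUE) vs single-network registration.
#' @param shared_regnet_weights share one parameter set across both cascade
#'   steps (incompatible with `two_step = FALSE`).
#' @param guided train with the semantic loss (FALSE forces `lambda_s = 0`;
#'   the U-Net then learns only through the deformation-loss gradient).
#' @param diffeomorphic predict stationary velocities and exponentiate by
#'   scaling and squaring.
#' @param pretrain_epochs optional epochs of U-Net-only training on the
#'   semantic loss before joint training.
#' @param freeze_unet freeze U-Net weights during joint training (only
#'   meaningful after pretraining).
#' @param unet_channels,regnet_channels base widths; `single_channels` is
#'   the single-step width chosen to match the cascade's parameter budget.
#' @param clip_norm global gradient-norm clipping threshold per optimizer
#'   step (stabilizes small-batch training; `Inf` disables).
#' @param adam_eps Adam denominator epsilon; values above the classical
#'   1e-8 damp noise-driven drift when gradients are near zero.
#' @param validate_every epochs between validation passes.
#' @param seed RNG seed controlling init, shuffling, and batching.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 5L,
                         lr = 0.001, beta1 = 0.97, clip_norm = 1.0,
                         adam_eps = 1e-5,
                         lambda_s = 1.0, lambda_r = 0.001,
                         kernel1 = 15L, kernel2 = 7L,
                         smooth_kernel = 3L, smooth_passes = 2L,
                         combine_mode = c("transform", "additive"),
                         two_step = TRUE, shared_regnet_weights = FALSE,
                         guided = TRUE, diffeomorphic = FALSE,
                         ss_steps = 6L,
                         pretrain_epochs = 0L, freeze_unet = FALSE,
                         unet_channels = 20L, regnet_channels = 48L,
                         single_channels = 68L,
                         validate_every = 5L, seed = 1L) {
  combine_mode <- match.arg(combine_mode)
  if (!two_step && shared_regnet_weights)
    stop("shared_regnet_weights requires two_step = TRUE")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  structure(as.list(environment()), class = "train_config")
}

new_adam <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_update <- function(st, theta, grads, lr, beta1, beta2 = 0.999,
                        eps = 1e-5) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g) || length(g) == 0L) next
    if (is.null(st$m[[nm]])) { st$m[[nm]] <- g * 0; st$v[[nm]] <- g * 0 }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    theta[[nm]] <- theta[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  theta
}

clip_grads <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g^2), numeric(1))))
  if (total <= clip_norm) return(grads)
  lapply(grads, function(g) if (is.null(g)) NULL else g * (clip_norm / total))
}

downsample_labels <- function(labels) {
  labels[seq(1L, nrow(labels), by = 2L), seq(1L, ncol(labels), by = 2L)]
}

# forward + backward for one pair; returns loss components and gradients
# (named by group: unet, net1, net2)
pair_step <- function(models, pair, w, cfg, compute_grads = TRUE) {
  lw_s <- if (cfg$guided) cfg$lambda_s else 0
  tape <- ad_tape()
  pn_u <- param_nodes(tape, models$unet$params)
  pn_1 <- param_nodes(tape, models$net1$params)
  pn_2 <- if (is.null(models$net2)) NULL
          else if (cfg$shared_regnet_weights) pn_1
          else param_nodes(tape, models$net2$params)
  ffn <- unet_forward(tape, models$unet, pn_u, ad_leaf(tape, as_cube(pair$fixed)))
  fmn <- unet_forward(tape, models$unet, pn_u, ad_leaf(tape, as_cube(pair$moving)))
  ls_f <- ad_weighted_ce(tape, ffn, downsample_labels(pair$fixed_labels), w)
  ls_m <- ad_weighted_ce(tape, fmn, downsample_labels(pair$moving_labels), w)
  casc <- cascade_forward(tape, models, pn_1, pn_2, ffn, fmn,
                          cfg$combine_mode, cfg$diffeomorphic, cfg$ss_steps)
  vfull <- upscale_field_node(tape, casc$v)
  L <- models$unet$cfg$num_labels
  sm1h <- one_hot(pair$moving_labels, L)
  sf1h <- one_hot(pair$fixed_labels, L)
  warped <- ad_warp(tape, ad_leaf(tape, sm1h), vfull)
  ld <- ad_weighted_l1(tape, sf1h, warped, w)
  vs <- vfull
  for (p in seq_len(cfg$smooth_passes)) vs <- ad_avgpool(tape, vs, cfg$smooth_kernel)
  lr_ <- ad_mean_sq(tape, ad_sub(tape, vfull, vs))
  total <- ad_axpy(tape, c(lw_s, lw_s, 1, cfg$lambda_r),
                   list(ls_f, ls_m, ld, lr_))
  out <- list(semantic_f = ls_f$value, semantic_m = ls_m$value,
              deform = ld$value, regular = lr_$value, total = total$value,
              v = vfull$value)
  if (!compute_grads) return(out)
  ad_backward(tape, total)
  collect <- function(pn, prefix) {
    gs <- lapply(pn, function(n) if (is.null(n$grad)) NULL else n$grad)
    setNames(gs, paste0(prefix, "/", names(pn)))
  }
  grads <- collect(pn_u, "unet")
  if (cfg$freeze_unet) grads <- lapply(grads, function(g) NULL)
  grads <- c(grads, collect(pn_1, "net1"))
  if (!is.null(pn_2) && !cfg$shared_regnet_weights)
    grads <- c(grads, collect(pn_2, "net2"))
  out$grads <- grads
  out
}

theta_from_models <- function(models, cfg) {
  th <- setNames(models$unet$params,
                 paste0("unet/", names(models$unet$params)))
  th <- c(th, setNames(models$net1$params,
                       paste0("net1/", names(models$net1$params))))
  if (!is.null(models$net2) && !cfg$shared_regnet_weights)
    th <- c(th, setNames(models$net2$params,
                         paste0("net2/", names(models$net2$params))))
  th
}

models_from_theta <- function(models, th, cfg) {
  pick <- function(prefix, template) {
    setNames(th[paste0(prefix, "/", names(template))], names(template))
  }
  models$unet$params <- pick("unet", models$unet$params)
  models$net1$params <- pick("net1", models$net1$params)
  if (!is.null(models$net2)) {
    models$net2$params <- if (cfg$shared_regnet_weights) models$net1$params
                          else pick("net2", models$net2$params)
  }
  models
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g))
    if (!is.null(g[[nm]]))
      total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  total
}

#' Train the registration model end-to-end
#'
#' Optimizes the U-Net and registration network(s) jointly under the total
#' loss on a set of training pairs. Fully seeded: two runs with the same
#' config and data produce identical checkpoints. Training aborts with an
#' informative error if the loss becomes non-finite.
#'
#' @param pairs list of `synthetic_pair`-like objects (fields `fixed`,
#'   `moving`, `fixed_labels`, `moving_labels`), or a manifest path / data
#'   frame from [make_dataset()] (its `train` split is used and `dir` must
#'   point to the dataset directory).
#' @param cfg a [train_config()].
#' @param val_pairs optional held-out pairs; validation mean Dice is logged
#'   every `cfg$validate_every` epochs and the best-epoch parameters kept.
#' @param dir dataset directory when `pairs` is a manifest.
#' @param checkpoint_path optional path; the final checkpoint is saved there
#'   with `saveRDS`.
#' @param log_path optional CSV path for per-step loss components.
#' @param verbose print epoch summaries.
#' @return a `semreg_checkpoint`: trained networks, config, label weights,
#'   loss log, validation history, and best-validation parameters.
#' @export
train_registration <- function(pairs, cfg = train_config(), val_pairs = NULL,
                               dir = NULL, checkpoint_path = NULL,
                               log_path = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.character(pairs)) {
    dir <- if (is.null(dir)) dirname(pairs) else dir
    pairs <- read.csv(pairs, stringsAsFactors = FALSE)
  }
  if (is.data.frame(pairs)) {
    if (is.null(dir)) stop("dir required when training from a manifest")
    man <- pairs
    if (is.null(val_pairs) && any(man$split == "test"))
      val_pairs <- lapply(which(man$split == "test"),
                          function(i) load_pair(man[i, ], dir))
    pairs <- lapply(which(man$split == "train"),
                    function(i) load_pair(man[i, ], dir))
  }
  n <- length(pairs)
  if (n < 1L) stop("no training pairs")
  d <- dim(pairs[[1]]$fixed)
  set.seed(cfg$seed)
  labs <- lapply(pairs, `[[`, "fixed_labels")
  L <- max(vapply(labs, max, 0L)) + 1L
  w <- class_weights(c(labs, lapply(pairs, `[[`, "moving_labels")), L)
  rcfg <- regnet_config(L, cfg$kernel1, cfg$kernel2, cfg$regnet_channels)
  models <- list(unet = build_feature_net(L, cfg$unet_channels))
  if (cfg$two_step) {
    models$net1 <- build_regnet(rcfg, step = 1L)
    models$net2 <- if (cfg$shared_regnet_weights) {
      n2 <- build_regnet(rcfg, step = 2L); n2$params <- models$net1$params; n2
    } else build_regnet(rcfg, step = 2L)
  } else {
    models$net1 <- build_regnet(rcfg, step = 1L,
                                base_channels = cfg$single_channels)
    models$net2 <- NULL
  }
  theta <- theta_from_models(models, cfg)
  adam <- new_adam()
  log <- list(); vhist <- list()
  best <- list(dice = -Inf, theta = NULL, epoch = NA_integer_)
  step_id <- 0L

  if (cfg$pretrain_epochs > 0L) {
    pt_adam <- new_adam()
    for (ep in seq_len(cfg$pretrain_epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        tape <- ad_tape()
        pn_u <- param_nodes(tape, models$unet$params)
        p <- pairs[[i]]
        lf <- ad_weighted_ce(tape,
                unet_forward(tape, models$unet, pn_u, ad_leaf(tape, as_cube(p$fixed))),
                downsample_labels(p$fixed_labels), w)
        lm <- ad_weighted_ce(tape,
                unet_forward(tape, models$unet, pn_u, ad_leaf(tape, as_cube(p$moving))),
                downsample_labels(p$moving_labels), w)
        tot <- ad_axpy(tape, c(1, 1), list(lf, lm))
        ad_backward(tape, tot)
        gs <- setNames(lapply(pn_u, function(nd) nd$grad),
                       names(models$unet$params))
        models$unet$params <- adam_update(pt_adam, models$unet$params, gs,
                                          cfg$lr, cfg$beta1,
                                          eps = cfg$adam_eps)
      }
    }
    theta <- theta_from_models(models, cfg)
  }

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (b in batches) {
      gacc <- NULL; comp <- c(0, 0, 0, 0, 0)
      for (i in b) {
        r <- pair_step(models, pairs[[i]], w, cfg)
        if (!is.finite(r$total))
          stop("non-finite loss at epoch ", ep, "; training aborted")
        gacc <- accumulate_grads(gacc, r$grads)
        comp <- comp + c(r$semantic_f, r$semantic_m, r$deform, r$regular,
                         r$total)
      }
      gacc <- lapply(gacc, function(g) if (is.null(g)) NULL else g / length(b))
      gacc <- clip_grads(gacc, cfg$clip_norm)
      theta <- adam_update(adam, theta, gacc, cfg$lr, cfg$beta1,
                           eps = cfg$adam_eps)
      models <- models_from_theta(models, theta, cfg)
      step_id <- step_id + 1L
      comp <- comp / length(b)
      log[[step_id]] <- data.frame(epoch = ep, step = step_id,
                                   l_semantic = comp[1] + comp[2],
                                   l_deform = comp[3], l_regular = comp[4],
                                   total = comp[5])
    }
    if (!is.null(val_pairs) &&
        (ep %% cfg$validate_every == 0L || ep == cfg$epochs)) {
      vd <- mean(vapply(val_pairs, function(p) {
        res <- checkpoint_infer(models, cfg, p$fixed, p$moving)
        evaluate_pair(p$fixed_labels, p$moving_labels, res$v, L)$mean_dice
      }, numeric(1)))
      vhist[[length(vhist) + 1L]] <- data.frame(epoch = ep, val_dice = vd)
      if (vd > best$dice) best <- list(dice = vd, theta = theta, epoch = ep)
      if (verbose)
        message(sprintf("epoch %d  total %.4f  val dice %.3f", ep,
                        comp[5], vd))
    } else if (verbose) {
      message(sprintf("epoch %d  total %.4f", ep, comp[5]))
    }
  }
  log <- do.call(rbind, log)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  ckpt <- structure(list(
    models = models, cfg = cfg, label_weights = w, num_labels = L,
    image_size = d, log = log,
    val_history = if (length(vhist)) do.call(rbind, vhist) else NULL,
    best = if (is.null(best$theta)) NULL else
      list(epoch = best$epoch, dice = best$dice,
           models = models_from_theta(models, best$theta, cfg))
  ), class = "semreg_checkpoint")
  if (!is.null(checkpoint_path)) saveRDS(ckpt, checkpoint_path)
  ckpt
}

# inference with explicit models (no label input)
checkpoint_infer <- function(models, cfg, fixed, moving,
                             moving_labels = NULL) {
  ff <- feature_forward(models$unet, fixed)
  fm <- feature_forward(models$unet, moving)
  if (is.null(models$net2))
    single_step_register(ff, fm, models$net1,
                         diffeomorphic = cfg$diffeomorphic,
                         moving_image = moving, moving_labels = moving_labels)
  else
    two_step_register(ff, fm, models$net1, models$net2,
                      combine_mode = cfg$combine_mode,
                      diffeomorphic = cfg$diffeomorphic,
                      moving_image = moving, moving_labels = moving_labels)
}

#' Register one image pair with a trained model
#'
#' Pure inference: a single forward pass, no label input. Images may be
#' given as matrices or file paths.
#'
#' @param fixed,moving `(H, W)` matrices in `[0, 1]`, or image file paths.
#' @param checkpoint a `semreg_checkpoint` or a path to one (`.rds`).
#' @param out_dir optional directory; writes the combined field
#'   (`field.rds`), the warped moving image (`warped_moving.png`) and, when
#'   labels are supplied, warped labels and an evaluation report JSON.
#' @param fixed_labels,moving_labels optional label matrices (or paths) used
#'   only for evaluation output.
#' @param use_best use the best-validation parameters if present.
#' @return a `registration_result` (fields `v1`, `v2`, `v`, warped outputs,
#'   and `report` when labels were supplied).
#' @export
register_pair <- function(fixed, moving, checkpoint, out_dir = NULL,
                          fixed_labels = NULL, moving_labels = NULL,
                          use_best = FALSE) {
  if (is.character(checkpoint)) checkpoint <- readRDS(checkpoint)
  stopifnot(inherits(checkpoint, "semreg_checkpoint"))
  if (is.character(fixed)) fixed <- read_image(fixed)
  if (is.character(moving)) moving <- read_image(moving)
  if (is.character(fixed_labels)) fixed_labels <- read_labels(fixed_labels)
  if (is.character(moving_labels)) moving_labels <- read_labels(moving_labels)
  if (!all(dim(fixed) == checkpoint$image_size))
    stop("image size ", paste(dim(fixed), collapse = "x"),
         " does not match checkpoint (",
         paste(checkpoint$image_size, collapse = "x"),
         "); resample the inputs or retrain")
  models <- if (use_best && !is.null(checkpoint$best))
    checkpoint$best$models else checkpoint$models
  res <- checkpoint_infer(models, checkpoint$cfg, fixed, moving,
                          moving_labels = moving_labels)
  if (!is.null(fixed_labels) && !is.null(moving_labels))
    res$report <- evaluate_pair(fixed_labels, moving_labels, res$v,
                                checkpoint$num_labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_field(res$v, file.path(out_dir, "field.rds"))
    write_image(res$warped_moving, file.path(out_dir, "warped_moving.png"))
    if (!is.null(res$warped_moving_labels))
      write_labels(res$warped_moving_labels,
                   file.path(out_dir, "warped_moving_labels.png"))
    if (!is.null(res$report))
      jsonlite::write_json(unclass(res$report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Evaluate a trained model over a set of labelled pairs
#'
#' Registers every pair and reports the Table-style column set: mean Dice,
#' per-structure Dice, contour distance, Jacobian standard deviation and
#' negative-Jacobian fraction. With `zero_field = TRUE` the unregistered
#' baseline is reported instead.
#'
#' @param pairs list of pairs, or a manifest path / data frame (the `test`
#'   split is used).
#' @param checkpoint a `semreg_checkpoint` or path; ignored when
#'   `zero_field = TRUE`.
#' @param dir dataset directory when `pairs` is a manifest.
#' @param zero_field evaluate the identity transform (no registration).
#' @param out optional path prefix; writes `<out>_pairs.csv` and
#'   `<out>_summary.json`.
#' @param use_best use best-validation parameters if present.
#' @return list with `per_pair` (data frame) and `summary` (named list of
#'   means).
#' @export
evaluate_manifest <- function(pairs, checkpoint = NULL, dir = NULL,
                              zero_field = FALSE, out = NULL,
                              use_best = FALSE) {
  if (is.character(pairs)) {
    dir <- if (is.null(dir)) dirname(pairs) else dir
    pairs <- read.csv(pairs, stringsAsFactors = FALSE)
  }
  if (is.data.frame(pairs)) {
    if (is.null(dir)) stop("dir required with a manifest")
    sel <- if (any(pairs$split == "test")) which(pairs$split == "test")
           else seq_len(nrow(pairs))
    pairs <- lapply(sel, function(i) load_pair(pairs[i, ], dir))
  }
  if (!zero_field && is.character(checkpoint)) checkpoint <- readRDS(checkpoint)
  L <- if (zero_field) max(vapply(pairs, function(p) max(p$fixed_labels), 0L)) + 1L
       else checkpoint$num_labels
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    fld <- if (zero_field) array(0, c(dim(p$fixed), 2L))
    else {
      models <- if (use_best && !is.null(checkpoint$best))
        checkpoint$best$models else checkpoint$models
      checkpoint_infer(models, checkpoint$cfg, p$fixed, p$moving)$v
    }
    rep <- suppressWarnings(
      evaluate_pair(p$fixed_labels, p$moving_labels, fld, L))
    data.frame(pair = i, mean_dice = rep$mean_dice,
               mean_contour_dist = rep$mean_contour_dist,
               jacobian_std = rep$jacobian_std,
               jacobian_negative_fraction = rep$jacobian_negative_fraction,
               t(setNames(rep$dice_per_label,
                          paste0("dice_l", seq_len(L - 1L)))))
  })
  per_pair <- do.call(rbind, rows)
  summary <- list(
    n_pairs = nrow(per_pair),
    mean_dice = mean(per_pair$mean_dice, na.rm = TRUE),
    mean_contour_dist = mean(per_pair$mean_contour_dist, na.rm = TRUE),
    mean_jacobian_std = mean(per_pair$jacobian_std),
    mean_jacobian_negative_fraction =
      mean(per_pair$jacobian_negative_fraction),
    dice_per_label = colMeans(per_pair[, paste0("dice_l", seq_len(L - 1L)),
                                       drop = FALSE], na.rm = TRUE)
  )
  if (!is.null(out)) {
    write.csv(per_pair, paste0(out, "_pairs.csv"), row.names = FALSE)
    jsonlite::write_json(summary, paste0(out, "_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(per_pair = per_pair, summary = summary)
}

#' @export
print.semreg_checkpoint <- function(x, ...) {
  cat("semreg checkpoint:",
      if (is.null(x$models$net2)) "single-step" else "two-step", "model,",
      x$num_labels, "labels,",
      paste(x$image_size, collapse = "x"), "images\n")
  np <- count_parameters(x$models$unet) + count_parameters(x$models$net1) +
    (if (is.null(x$models$net2) || x$cfg$shared_regnet_weights) 0
     else count_parameters(x$models$net2))
  cat(sprintf("  %d trainable parameters, %d epochs trained\n",
              np, max(x$log$epoch)))
  if (!is.null(x$val_history))
    cat(sprintf("  final validation Dice %.4f\n",
                x$val_history$val_dice[nrow(x$val_history)]))
  invisible(x)
}
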