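# Network containers. A network is a list of 3x3 convolution layer specs plus
# a flat named parameter list (weight matrices (kh*kw*cin) x cout and bias
# vectors), initialized with He-scaled Gaussians; prediction heads can be
# zero-initialized so training starts from the identity transform.

conv_spec <- function(name, cin, cout, stride = 1L, k = 3L,
                      activation = "leaky_relu", zero_init = FALSE) {
  list(name = name, k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride),
       pad = (as.integer(k) - 1L) %/% 2L,
       activation = activation, zero_init = zero_init)
}

init_params <- function(layers) {
  params <- list()
  for (ly in layers) {
    fan_in <- ly$k * ly$k * ly$cin
    w <- if (ly$zero_init) matrix(0, fan_in, ly$cout)
         else matrix(rnorm(fan_in * ly$cout, sd = sqrt(2 / fan_in)),
                     fan_in, ly$cout)
    params[[paste0("w.", ly$name)]] <- w
    params[[paste0("b.", ly$name)]] <- numeric(ly$cout)
  }
  params
}

new_network <- function(type, layers, cfg) {
  structure(list(type = type, layers = layers, params = init_params(layers),
                 cfg = cfg),
            class = "semreg_net")
}

#' Number of trainable parameters of a network
#'
#' @param net a network built by [build_feature_net()] or [build_regnet()],
#'   or a bare parameter list.
#' @return integer parameter count (weights + biases).
#' @export
count_parameters <- function(net) {
  params <- if (inherits(net, "semreg_net")) net$params else net
  sum(vapply(params, length, integer(1)))
}

# lift a parameter list onto a tape as leaf nodes
param_nodes <- function(tape, params) lapply(params, ad_leaf, tape = tape)

run_conv <- function(tape, pn, layers, name, x, need_gx = TRUE) {
  ly <- layers[[name]]
  y <- ad_conv(tape, x, pn[[paste0("w.", name)]], pn[[paste0("b.", name)]],
               ly$k, ly$k, ly$stride, ly$pad, need_gx = need_gx)
  if (identical(ly$activation, "leaky_relu")) ad_leaky_relu(tape, y) else y
}

named_layers <- function(layers) setNames(layers, vapply(layers, `[[`, "", "name"))

# ---- semantic feature U-Net ----------------------------------------------

#' Build the semantic feature-extraction U-Net
#'
#' An 11-convolution (3x3) encoder--decoder with three stride-2 downsampling
#' convolutions, two nearest-neighbour upsampling stages and two skip
#' connections. The output is at half the input resolution with `num_labels`
#' softmax channels (per-pixel class probabilities). Channel widths double at
#' each downsampling stage, scaled by `base_channels`; the default lands near
#' 200k trainable parameters. LeakyReLU(0.1) activations, no normalization
#' layers.
#'
#' @param num_labels number of classes L (including background), >= 2.
#' @param base_channels width of the first stage (default 20).
#' @return a network object; apply with [feature_forward()].
#' @export
build_feature_net <- function(num_labels, base_channels = 20L) {
  if (num_labels < 2L) stop("num_labels must be >= 2")
  c1 <- as.integer(base_channels); c2 <- 2L * c1; c3 <- 4L * c1
  layers <- named_layers(list(
    conv_spec("d1", 1L, c1, stride = 2L),
    conv_spec("d2", c1, c1),
    conv_spec("d3", c1, c2, stride = 2L),
    conv_spec("d4", c2, c2),
    conv_spec("d5", c2, c3, stride = 2L),
    conv_spec("d6", c3, c3),
    conv_spec("u1", c3, c2),
    conv_spec("m1", 2L * c2, c2),
    conv_spec("u2", c2, c1),
    conv_spec("m2", 2L * c1, c1),
    conv_spec("out", c1, as.integer(num_labels), activation = "none")
  ))
  new_network("unet", layers,
              list(num_labels = as.integer(num_labels),
                   base_channels = c1, activation = "leaky_relu(0.1)",
                   normalization = "none"))
}

unet_forward <- function(tape, net, pn, x) {
  L <- net$layers
  h1 <- run_conv(tape, pn, L, "d1", x, need_gx = FALSE)  # H/2 (image is a leaf)
  h2 <- run_conv(tape, pn, L, "d2", h1)           # H/2 (skip)
  h3 <- run_conv(tape, pn, L, "d3", h2)           # H/4
  h4 <- run_conv(tape, pn, L, "d4", h3)           # H/4 (skip)
  h5 <- run_conv(tape, pn, L, "d5", h4)           # H/8
  h6 <- run_conv(tape, pn, L, "d6", h5)           # H/8
  u1 <- run_conv(tape, pn, L, "u1", ad_upsample_nearest(tape, h6, 2L))
  m1 <- run_conv(tape, pn, L, "m1", ad_concat(tape, u1, h4))
  u2 <- run_conv(tape, pn, L, "u2", ad_upsample_nearest(tape, m1, 2L))
  m2 <- run_conv(tape, pn, L, "m2", ad_concat(tape, u2, h2))
  ad_softmax(tape, run_conv(tape, pn, L, "out", m2))
}

#' Extract semantic features (class probabilities) from an image
#'
#' Runs the U-Net forward; input height and width must be divisible by 8
#' (three stride-2 stages). Weights are shared between fixed and moving
#' images by construction: the same network instance processes both.
#'
#' @param net a network from [build_feature_net()].
#' @param image `(H, W)` matrix of intensities in `[0, 1]`.
#' @return `(H/2, W/2, L)` array of softmax probabilities.
#' @export
feature_forward <- function(net, image) {
  stopifnot(inherits(net, "semreg_net"), net$type == "unet")
  d <- dim(image)
  if (any(d[1:2] %% 8L != 0L)) stop("image dimensions must be divisible by 8")
  tape <- ad_tape()
  pn <- param_nodes(tape, net$params)
  out <- unet_forward(tape, net, pn, ad_leaf(tape, as_cube(image)))
  out$value
}

# ---- registration network -------------------------------------------------

#' Configuration for the registration cascade
#'
#' Both cascade steps use the same encoder architecture (six 3x3 convolutions
#' plus a 2-channel prediction head); they differ in stride placement so that
#' the first step predicts a coarser control grid (larger B-spline scale,
#' large deformations) and the second a finer one (refinement). The control-
#' grid spacing at feature resolution is `(kernel + 1) / 2`, rounded down to
#' a power of two so it is reachable by stride-2 convolutions.
#'
#' @param num_labels L; the networks see `2 L` concatenated feature channels.
#' @param kernel1,kernel2 odd B-spline pooling sizes of step 1 and 2 (coarse
#'   to fine, `kernel1 >= kernel2`). Defaults 15 and 7 suit 64 px images
#'   (spacings 8 and 4 at feature resolution); at the 320 px face scale the
#'   corresponding choices are 19 and 11.
#' @param base_channels encoder width (default 48; the two-step cascade then
#'   has about 1.9M parameters, the single-step default 68 matches it).
#' @return a `regnet_config` list.
#' @export
regnet_config <- function(num_labels, kernel1 = 15L, kernel2 = 7L,
                          base_channels = 48L) {
  k1 <- check_odd_kernel(kernel1); k2 <- check_odd_kernel(kernel2)
  if (k1 < k2) stop("kernel1 must be >= kernel2 (coarse to fine)")
  sp <- function(k) 2L^max(1L, floor(log2((k + 1L) / 2L)))
  structure(list(num_labels = as.integer(num_labels),
                 kernel1 = k1, kernel2 = k2,
                 spacing1 = sp(k1), spacing2 = sp(k2),
                 base_channels = as.integer(base_channels)),
            class = "regnet_config")
}

#' Build one registration network
#'
#' A strided convolutional encoder mapping concatenated semantic features
#' (`2 L` channels at half image resolution) to a 2-channel B-spline control
#' grid at the configured spacing. The prediction head is zero-initialized so
#' the initial transform is the identity.
#'
#' @param cfg a [regnet_config()].
#' @param step cascade step (1 = coarse, 2 = fine); selects the control-grid
#'   spacing.
#' @param base_channels optional width override (used by the single-step
#'   variant to match the cascade's parameter budget).
#' @return a network object.
#' @export
build_regnet <- function(cfg, step = 1L, base_channels = cfg$base_channels) {
  stopifnot(inherits(cfg, "regnet_config"))
  spacing <- if (step == 1L) cfg$spacing1 else cfg$spacing2
  if (!spacing %in% c(2L, 4L, 8L))
    stop("control-grid spacing ", spacing, " unsupported (must be 2, 4 or 8)")
  cin <- 2L * cfg$num_labels
  c1 <- as.integer(base_channels); c2 <- 2L * c1; c3 <- 4L * c1
  s4 <- if (spacing >= 4L) 2L else 1L
  s6 <- if (spacing == 8L) 2L else 1L
  layers <- named_layers(list(
    conv_spec("e1", cin, c1),
    conv_spec("e2", c1, c2, stride = 2L),
    conv_spec("e3", c2, c2),
    conv_spec("e4", c2, c3, stride = s4),
    conv_spec("e5", c3, c3),
    conv_spec("e6", c3, c3, stride = s6),
    conv_spec("head", c3, 2L, activation = "none", zero_init = TRUE)
  ))
  new_network("regnet", layers,
              list(num_labels = cfg$num_labels, spacing = spacing,
                   kernel = if (step == 1L) cfg$kernel1 else cfg$kernel2,
                   step = as.integer(step), base_channels = c1))
}

regnet_forward <- function(tape, net, pn, x) {
  L <- net$layers
  h <- x
  for (nm in c("e1", "e2", "e3", "e4", "e5", "e6", "head"))
    h <- run_conv(tape, pn, L, nm, h)
  h
}

# predict a dense field at feature resolution from two feature-map nodes;
# returns the field node. cfg entries used: spacing, kernel; diffeo applies
# scaling-and-squaring to the densified output (velocity reading).
regnet_field <- function(tape, net, pn, ffn, fmn, diffeo = FALSE,
                         ss_steps = 6L) {
  ctrl <- regnet_forward(tape, net, pn, ad_concat(tape, ffn, fmn))
  d <- dim(ffn$value)
  s <- net$cfg$spacing; k <- net$cfg$kernel
  up <- ad_upsample_nearest(tape, ctrl, s)
  du <- dim(up$value)
  fld <- ad_crop(tape, up, (du[1] - d[1]) %/% 2L, (du[2] - d[2]) %/% 2L,
                 d[1], d[2])
  for (p in 1:3) fld <- ad_avgpool(tape, fld, k)
  if (diffeo) fld <- ad_scaling_and_squaring(tape, fld, ss_steps)
  fld
}
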