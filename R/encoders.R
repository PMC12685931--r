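# ---------------------------------------------------------------------------
# Simplified multi-scale convolutional encoders.
#
# Three encoders share one blueprint: an Attention Mapper Encoder (plus an
# EMA twin used for support images), a Support Set Encoder (2 input channels:
# image + mask) and a Segmentation Encoder. The blueprint deliberately keeps
# receptive fields small so that attention maps remain spatially specific:
# every convolution is 1x1 except the stem's two 3x3 convolutions, each
# stage's 3x3 stride-2 downsampler, and a single 3x3 depthwise convolution in
# the first feed-forward block of each stage. This fixes the receptive field
# after stem/stages 1-4 at 7/19/43/91/187 px on a 256-px axis regardless of
# stage depths.
# ---------------------------------------------------------------------------

#' Encoder configuration
#'
#' @param in_channels 1 for image-only encoders, 2 for the support encoder
#'   (image and mask concatenated along channels).
#' @param stage_widths integer vector of 4 channel counts.
#' @param stage_depths integer vector of 4 block counts.
#' @param preset `"paper"` (depths 3,3,5,2; widths 64,128,256,512) or
#'   `"tiny"` (depths 1,1,1,1; widths 8,16,24,32); explicit widths/depths
#'   override the preset.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(in_channels = 1L,
                           stage_widths = NULL,
                           stage_depths = NULL,
                           preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    paper = list(widths = c(64L, 128L, 256L, 512L), depths = c(3L, 3L, 5L, 2L)),
    tiny  = list(widths = c(8L, 16L, 24L, 32L),     depths = c(1L, 1L, 1L, 1L)))
  stage_widths <- as.integer(stage_widths %||% defaults$widths)
  stage_depths <- as.integer(stage_depths %||% defaults$depths)
  if (length(stage_widths) != 4L || length(stage_depths) != 4L)
    stop("encoder requires exactly 4 stages (got ",
         length(stage_widths), " widths, ", length(stage_depths), " depths)")
  if (any(stage_widths <= 0L) || any(stage_depths <= 0L))
    stop("stage widths and depths must be positive")
  if (!in_channels %in% c(1L, 2L))
    stop("in_channels must be 1 (image) or 2 (image + mask)")
  structure(list(in_channels = as.integer(in_channels),
                 stage_widths = stage_widths,
                 stage_depths = stage_depths,
                 stem_width = max(2L, stage_widths[1] %/% 2L),
                 preset = preset),
            class = "encoder_config")
}

#' Build an encoder
#'
#' Instantiates parameters for the simplified encoder blueprint and records
#' the convolutional layer sequence used for receptive-field accounting.
#'
#' @param config an [encoder_config()].
#' @return an `icseg_encoder` with `$params` (autodiff leaves) and `$layers`.
#' @export
build_encoder <- function(config) {
  if (!inherits(config, "encoder_config")) config <- do.call(encoder_config, config)
  P <- list()
  layers <- list()
  add_layer <- function(stage, k, stride)
    layers[[length(layers) + 1L]] <<- list(stage = stage, k = k, stride = stride)

  ws <- config$stem_width
  P$stem1_w <- ag_param(init_conv_w(ws, config$in_channels, 3L))
  P$stem1_b <- ag_param(numeric(ws))
  add_layer("stem", 3L, 2L)
  P$stem2_w <- ag_param(init_conv_w(ws, ws, 3L))
  P$stem2_b <- ag_param(numeric(ws))
  add_layer("stem", 3L, 1L)

  cin <- ws
  for (i in 1:4) {
    w <- config$stage_widths[i]
    sl <- paste0("stage", i)
    P[[paste0("s", i, "_down_w")]] <- ag_param(init_conv_w(w, cin, 3L))
    P[[paste0("s", i, "_down_b")]] <- ag_param(numeric(w))
    add_layer(sl, 3L, 2L)
    for (j in seq_len(config$stage_depths[i])) {
      pre <- paste0("s", i, "_b", j, "_")
      # token mixer: LN -> 1x1 -> GELU -> 1x1 (zero-init), residual
      P[[paste0(pre, "m1_w")]] <- ag_param(init_conv_w(w, w, 1L))
      P[[paste0(pre, "m1_b")]] <- ag_param(numeric(w))
      add_layer(sl, 1L, 1L)
      P[[paste0(pre, "m2_w")]] <- ag_param(matrix(0, w, w))
      P[[paste0(pre, "m2_b")]] <- ag_param(numeric(w))
      add_layer(sl, 1L, 1L)
      # FFN: LN -> 1x1 -> [3x3 depthwise in first block] -> GELU -> 1x1 (zero)
      P[[paste0(pre, "f1_w")]] <- ag_param(init_conv_w(w, w, 1L))
      P[[paste0(pre, "f1_b")]] <- ag_param(numeric(w))
      add_layer(sl, 1L, 1L)
      if (j == 1L) {
        P[[paste0(pre, "dw_w")]] <- ag_param(matrix(stats::rnorm(9L * w, sd = sqrt(2 / 9)), 9L, w))
        P[[paste0(pre, "dw_b")]] <- ag_param(numeric(w))
        add_layer(sl, 3L, 1L)
      }
      P[[paste0(pre, "f2_w")]] <- ag_param(matrix(0, w, w))
      P[[paste0(pre, "f2_b")]] <- ag_param(numeric(w))
      add_layer(sl, 1L, 1L)
    }
    cin <- w
  }
  structure(list(config = config, params = P, layers = layers),
            class = "icseg_encoder")
}

# Forward pass. `override` substitutes parameter values (plain arrays) while
# reusing the encoder's structure: used for the EMA twin and for the
# receptive-field probe. `probe = TRUE` replaces the network by its linearized
# positive-weight skeleton (no LayerNorm, identity activations, uniform
# positive kernels) so that the gradient support equals the convolutional
# receptive field exactly.
encoder_forward <- function(enc, x, override = NULL, probe = FALSE,
                            stop_after = NULL) {
  cfg <- enc$config
  getp <- function(name) {
    if (!is.null(override)) return(ag_const(override[[name]]))
    enc$params[[name]]
  }
  pw <- function(name, k, cin_eff) {
    p <- getp(name)
    if (probe) ag_const(matrix(1 / (k * k * cin_eff), nrow(p$val), ncol(p$val))) else p
  }
  pb <- function(name) {
    p <- getp(name)
    if (probe) ag_const(numeric(length(p$val))) else p
  }
  act <- if (probe) identity else ag_gelu
  norm <- if (probe) identity else ag_layernorm

  levels <- list()
  d <- dim(ag_val(x)); stopifnot(length(d) == 4L)
  if (d[3] != cfg$in_channels)
    stop("encoder expects ", cfg$in_channels, " input channel(s), got ", d[3])
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial size must be divisible by 32, got ", d[1], "x", d[2])

  ws <- cfg$stem_width
  h <- ag_conv2d(x, pw("stem1_w", 3L, cfg$in_channels), pb("stem1_b"), 3L, 2L, 1L)
  h <- act(h)
  h <- ag_conv2d(h, pw("stem2_w", 3L, ws), pb("stem2_b"), 3L, 1L, 1L)
  levels[["2"]] <- norm(h)
  if (identical(stop_after, "stem")) return(list(levels = levels, last = h))

  cin <- ws
  for (i in 1:4) {
    w <- cfg$stage_widths[i]
    h <- ag_conv2d(h, pw(paste0("s", i, "_down_w"), 3L, cin), pb(paste0("s", i, "_down_b")), 3L, 2L, 1L)
    for (j in seq_len(cfg$stage_depths[i])) {
      pre <- paste0("s", i, "_b", j, "_")
      u <- norm(h)
      u <- ag_conv2d(u, pw(paste0(pre, "m1_w"), 1L, w), pb(paste0(pre, "m1_b")), 1L)
      u <- act(u)
      u <- ag_conv2d(u, pw(paste0(pre, "m2_w"), 1L, w), pb(paste0(pre, "m2_b")), 1L)
      h <- ag_add(h, u)
      v <- norm(h)
      v <- ag_conv2d(v, pw(paste0(pre, "f1_w"), 1L, w), pb(paste0(pre, "f1_b")), 1L)
      if (j == 1L) {
        dwp <- getp(paste0(pre, "dw_w"))
        dww <- if (probe) ag_const(matrix(1 / 9, 9L, w)) else dwp
        v <- ag_dwconv2d(v, dww, pb(paste0(pre, "dw_b")))
      }
      v <- act(v)
      v <- ag_conv2d(v, pw(paste0(pre, "f2_w"), 1L, w), pb(paste0(pre, "f2_b")), 1L)
      h <- ag_add(h, v)
    }
    levels[[as.character(2L^(i + 1L))]] <- norm(h)
    if (identical(stop_after, paste0("stage", i))) break
    cin <- w
  }
  list(levels = levels, last = h)
}

#' Encode a query image into a feature pyramid
#'
#' @param encoder an `icseg_encoder` built with 1 input channel.
#' @param image numeric matrix (H x W), values expected in `[0, 1]`.
#' @return a `feature_pyramid`: LayerNorm-normalized levels at output strides
#'   2, 4, 8, 16, 32, each an (H/os, W/os, C, 1) array.
#' @export
encode_query <- function(encoder, image) {
  if (!is.matrix(image)) stop("query image must be a 2D matrix")
  x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
  fp <- encoder_forward(encoder, ag_const(x))
  structure(list(levels = lapply(fp$levels, ag_val), source = "query"),
            class = "feature_pyramid")
}

#' Encode a support set
#'
#' Concatenates each support image with its binary mask along the channel
#' axis (image first, mask second) and encodes all S pairs independently.
#'
#' @param encoder an `icseg_encoder` built with 2 input channels.
#' @param images list of S image matrices.
#' @param masks list of S binary mask matrices (values 0/1).
#' @return a `feature_pyramid` whose levels have shape (H/os, W/os, C, S).
#' @export
encode_support <- function(encoder, images, masks) {
  if (length(images) != length(masks))
    stop("episode error: ", length(images), " images vs ", length(masks), " masks")
  S <- length(images)
  for (m in masks) {
    if (!all(m %in% c(0, 1))) stop("support masks must be binary (0/1)")
  }
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 2L, S))
  for (s in seq_len(S)) {
    x[, , 1L, s] <- images[[s]]
    x[, , 2L, s] <- masks[[s]]
  }
  fp <- encoder_forward(encoder, ag_const(x))
  structure(list(levels = lapply(fp$levels, ag_val), source = "support"),
            class = "feature_pyramid")
}

# ------------------------------- EMA teacher --------------------------------

#' Initialize an EMA (teacher) state from an encoder
#'
#' @param encoder the online encoder whose parameters are copied.
#' @param decay EMA decay in `[0, 1]`.
#' @return an `ema_state` with `$decay` and `$shadow` (plain arrays).
#' @export
ema_init <- function(encoder, decay = 0.999) {
  stopifnot(decay >= 0, decay <= 1)
  structure(list(decay = decay, shadow = lapply(encoder$params, ag_val)),
            class = "ema_state")
}

#' One EMA update step
#'
#' Each shadow parameter becomes `decay * shadow + (1 - decay) * online`.
#'
#' @param state an `ema_state`.
#' @param online_params named list of online parameters (autodiff tensors or
#'   plain arrays) matching the shadow collection.
#' @return the updated `ema_state`.
#' @export
ema_update <- function(state, online_params) {
  nm <- names(state$shadow)
  if (!identical(nm, names(online_params)))
    stop("EMA state error: parameter collections do not match")
  d <- state$decay
  for (k in nm) {
    ov <- ag_val(online_params[[k]])
    if (!identical(dim(state$shadow[[k]]) %||% length(state$shadow[[k]]),
                   dim(ov) %||% length(ov)))
      stop("EMA state error: shape mismatch for ", k)
    state$shadow[[k]] <- d * state$shadow[[k]] + (1 - d) * ov
  }
  state
}

# --------------------------- receptive fields -------------------------------

#' Theoretical receptive field per encoder stage
#'
#' Closed-form accumulation `r <- r + (k - 1) * j; j <- j * stride` over the
#' recorded convolutional layer sequence (normalization and activation
#' layers do not alter the receptive field).
#'
#' @param encoder an `icseg_encoder`.
#' @param input_size reference input axis length for the fraction column.
#' @return data.frame with stage, rf_px and fraction (rf_px / input_size).
#' @export
theoretical_receptive_field <- function(encoder, input_size = 256L) {
  r <- 1; j <- 1
  stages <- c("stem", paste0("stage", 1:4))
  out <- stats::setNames(numeric(length(stages)), stages)
  for (ly in encoder$layers) {
    r <- r + (ly$k - 1) * j
    j <- j * ly$stride
    out[ly$stage] <- r
  }
  data.frame(stage = stages, rf_px = as.numeric(out),
             fraction = as.numeric(out) / input_size,
             row.names = NULL)
}

#' Empirical receptive field via gradient masking
#'
#' Runs the encoder in a linearized probe mode (uniform positive kernels, no
#' normalization, identity activations) on a width-reduced clone with the
#' same layer layout, and measures the spatial support of the input gradient
#' of a central output unit. With strictly positive weights the gradient is
#' nonzero exactly on the receptive field.
#'
#' @param encoder an `icseg_encoder` (layout source; widths are irrelevant).
#' @param stage one of `"stem"`, `"stage1"` ... `"stage4"`.
#' @param input_size input axis length (must exceed the receptive field).
#' @return receptive field extent in pixels (max over both axes).
#' @export
empirical_receptive_field <- function(encoder, stage = "stage4", input_size = 256L) {
  cfg <- encoder$config
  thin <- build_encoder(encoder_config(in_channels = 1L,
                                       stage_widths = c(2L, 2L, 2L, 2L),
                                       stage_depths = cfg$stage_depths,
                                       preset = cfg$preset))
  x <- ag_tensor(array(0, c(input_size, input_size, 1L, 1L)), requires_grad = TRUE)
  fp <- encoder_forward(thin, x, probe = TRUE, stop_after = stage)
  out <- fp$last
  d <- dim(out$val)
  ch <- d[1] %/% 2L; cw <- d[2] %/% 2L
  sel <- array(0, d); sel[ch, cw, , 1] <- 1
  loss <- ag_sum(ag_mul(out, ag_const(sel)))
  ag_backward(loss)
  g <- abs(x$grad[, , 1, 1])
  rows <- which(rowSums(g) > 0)
  cols <- which(colSums(g) > 0)
  max(diff(range(rows)) + 1L, diff(range(cols)) + 1L)
}
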