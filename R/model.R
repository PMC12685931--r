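# ---------------------------------------------------------------------------
# Full model: three encoders + EMA teacher + cross-attention mapper +
# attention upsamplers + segmentation decoder.
# ---------------------------------------------------------------------------

#' Build an in-context segmentation model
#'
#' @param preset encoder preset, `"tiny"` (desk-scale tests) or `"paper"`.
#' @param n_registry number of registry tokens in the cross-attention mapper.
#' @param c_init initial nearest/bilinear mix for the attention upsamplers.
#' @param ema_decay decay for the EMA twin of the attention mapper encoder.
#' @param stage_widths,stage_depths optional overrides of the preset.
#' @param seed optional integer; when given, parameter initialization is
#'   reproducible.
#' @return an `icseg_model`.
#' @export
icseg_model <- function(preset = c("tiny", "paper"), n_registry = 4L,
                        c_init = 0.5, ema_decay = 0.999,
                        stage_widths = NULL, stage_depths = NULL, seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  cfg1 <- encoder_config(1L, stage_widths, stage_depths, preset)
  cfg2 <- encoder_config(2L, stage_widths, stage_depths, preset)
  w <- cfg1$stage_widths
  m <- list(
    config = list(preset = preset, n_registry = as.integer(n_registry),
                  c_init = c_init, ema_decay = ema_decay,
                  stage_widths = cfg1$stage_widths, stage_depths = cfg1$stage_depths),
    enc_map = build_encoder(cfg1),
    enc_sup = build_encoder(cfg2),
    enc_seg = build_encoder(cfg1),
    attn = cross_attention_params(w[4], n_registry),
    ups16 = upsampler_params(w[3], c_init),
    ups8 = upsampler_params(w[2], c_init),
    dec = decoder_params(cfg1)
  )
  m$ema <- ema_init(m$enc_map, ema_decay)
  class(m) <- "icseg_model"
  m
}

#' Collect trainable parameters
#'
#' Named flat list of every autodiff leaf except the EMA shadow (which
#' receives no gradients).
#'
#' @param model an `icseg_model`.
#' @return named list of `ag_tensor` leaves.
#' @export
collect_params <- function(model) {
  out <- list()
  add <- function(prefix, lst) {
    for (nm in names(lst)) {
      if (is_ag(lst[[nm]])) out[[paste0(prefix, ".", nm)]] <<- lst[[nm]]
    }
  }
  add("map", model$enc_map$params)
  add("sup", model$enc_sup$params)
  add("seg", model$enc_seg$params)
  add("attn", model$attn[c("W_Q", "W_K", "tau", "registry")])
  add("ups16", model$ups16[c("u", "ffn_w1", "ffn_b1", "ffn_w2", "ffn_b2")])
  add("ups8", model$ups8[c("u", "ffn_w1", "ffn_b1", "ffn_w2", "ffn_b2")])
  add("dec", model$dec)
  out
}

count_params <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$val), numeric(1)))
}

# episode sanity checks shared by forward/training
validate_episode <- function(episode) {
  stopifnot(is.matrix(episode$query_image))
  S <- length(episode$support_images)
  if (S < 1L) stop("episode error: empty support set")
  if (length(episode$support_masks) != S)
    stop("episode error: ", S, " support images vs ",
         length(episode$support_masks), " masks")
  invisible(episode)
}

# Full forward pass. Returns autodiff logits plus plain-value extras.
model_forward <- function(model, episode, K_base = 8L, export_attention = FALSE) {
  validate_episode(episode)
  q <- episode$query_image
  H <- nrow(q); W <- ncol(q)
  S <- length(episode$support_images)
  qx <- ag_const(array(q, c(H, W, 1L, 1L)))
  sx <- array(0, c(H, W, 2L, S))
  si <- array(0, c(H, W, 1L, S))
  for (s in seq_len(S)) {
    sx[, , 1L, s] <- episode$support_images[[s]]
    sx[, , 2L, s] <- episode$support_masks[[s]]
    si[, , 1L, s] <- episode$support_images[[s]]
  }
  fp_map_q <- encoder_forward(model$enc_map, qx)
  fp_map_s <- encoder_forward(model$enc_map, ag_const(si),
                              override = model$ema$shadow)
  fp_sup <- encoder_forward(model$enc_sup, ag_const(sx))
  fp_seg <- encoder_forward(model$enc_seg, qx)

  g32 <- dim(ag_val(fp_map_q$levels[["32"]]))
  Xq32 <- ag_flatten_hw(fp_map_q$levels[["32"]])
  Xs32 <- ag_flatten_hw(fp_map_s$levels[["32"]])
  A32 <- .attn_coarse(model$attn, Xq32, Xs32, S, g32[1], g32[2])

  Xq16 <- ag_flatten_hw(fp_map_q$levels[["16"]])
  Xs16 <- ag_flatten_hw(fp_map_s$levels[["16"]])
  A16 <- .attn_upsample(A32, model$ups16, Xq16, Xs16, K = 4L * K_base)

  Xq8 <- ag_flatten_hw(fp_map_q$levels[["8"]])
  Xs8 <- ag_flatten_hw(fp_map_s$levels[["8"]])
  A8 <- .attn_upsample(A16, model$ups8, Xq8, Xs8, K = 16L * K_base)

  logits <- .decode_forward(model$dec, fp_seg$levels, fp_sup$levels, A32, A16, A8)
  prob <- 1 / (1 + exp(-ag_val(logits)[, , 1, 1]))
  out <- list(logits = logits, prob = prob)
  if (export_attention) {
    strip <- function(a) { a$A <- ag_val(a$A); a }
    out$stage_attention <- list(stride32 = strip(A32), stride16 = strip(A16),
                                stride8 = strip(A8))
  }
  out
}

#' Segment a query image given a support set
#'
#' @param model a (typically trained) `icseg_model`.
#' @param episode list with `query_image`, `support_images`, `support_masks`.
#' @param K_base base top-K for the attention upsamplers; the effective
#'   number of refined locations is `4*K_base` at stride 16 and `16*K_base`
#'   at stride 8.
#' @param export_attention also return the per-stage attention maps for
#'   inspection/explainability.
#' @return list with `mask` (probabilities in `[0, 1]`, query-sized) and
#'   optionally `stage_attention`.
#' @export
predict_episode <- function(model, episode, K_base = 8L, export_attention = FALSE) {
  res <- model_forward(model, episode, K_base = K_base,
                       export_attention = export_attention)
  out <- list(mask = res$prob)
  if (export_attention) out$stage_attention <- res$stage_attention
  out
}

# ------------------------------- checkpoints --------------------------------

#' Save a model checkpoint
#'
#' @param model an `icseg_model`.
#' @param path destination file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  params <- lapply(collect_params(model), ag_val)
  obj <- list(format = "icseg-checkpoint-1", config = model$config,
              params = params, ema = model$ema$shadow,
              ema_decay = model$ema$decay)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return an `icseg_model` with restored weights.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "icseg-checkpoint-1"))
    stop("not an icseg checkpoint: ", path)
  cfg <- obj$config
  model <- icseg_model(preset = cfg$preset, n_registry = cfg$n_registry,
                       c_init = cfg$c_init, ema_decay = cfg$ema_decay,
                       stage_widths = cfg$stage_widths,
                       stage_depths = cfg$stage_depths)
  pl <- collect_params(model)
  if (!setequal(names(pl), names(obj$params)))
    stop("checkpoint parameter names do not match the model")
  for (nm in names(pl)) pl[[nm]]$val <- obj$params[[nm]]
  model$ema$shadow <- obj$ema
  model$ema$decay <- obj$ema_decay
  model
}
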