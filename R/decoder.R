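# ---------------------------------------------------------------------------
# Segmentation decoder: five residual stages plus a final head.
#
# Stage 1 fuses at stride 32 using the coarse attention map; stages 2-3
# upscale the query features (3x3 stride-2 transposed convolutions), upsample
# the attention map and fuse again at strides 16 and 8; stages 4-5 upscale
# with query skip connections only; the head upsamples stride 2 -> 1 and
# projects to a single sigmoid channel. Support information enters the
# decoder exclusively through the Provided-Attention blocks:
#     X_i^q := X_i^q + (A_i . X^s) W_p + b_p
# so zeroing the attention map severs all influence of the support masks.
# All inner residual blocks have zero-initialized last layers (identity at
# initialization); LayerNorm is a per-sample z-score over (C, H, W).
# ---------------------------------------------------------------------------

#' Provided-attention block parameters
#'
#' Zero-initialized projection, so the block starts as the identity.
#'
#' @param d channel count at the decoder stage.
#' @return list with `W_p` (d x d) and `b_p` (length d), autodiff leaves.
#' @export
provided_attention_params <- function(d) {
  structure(list(W_p = ag_param(matrix(0, d, d)),
                 b_p = ag_param(numeric(d)),
                 d = as.integer(d)),
            class = "provided_attention_params")
}

.pa_apply <- function(Xq, A, Xs, params) {
  Xq <- as_ag(Xq); A <- as_ag(A); Xs <- as_ag(Xs)
  pooled <- ag_matmul(A, Xs)                       # (rows, d)
  upd <- ag_dense(pooled, ag_t(params$W_p), params$b_p)  # pooled %*% W_p + b_p
  ag_add(Xq, upd)
}

#' Apply a Provided-Attention block
#'
#' Residual update `X_i^q := X_i^q + (A_i . X^s) W_p + b_p` for every query
#' row.
#'
#' @param X_q (rows x d) query feature matrix.
#' @param A attention matrix whose column count equals `nrow(X_s)`.
#' @param X_s (S*rows' x d) support feature matrix.
#' @param params a [provided_attention_params()] object.
#' @return updated query feature matrix.
#' @export
provided_attention_apply <- function(X_q, A, X_s, params) {
  X_q <- as.matrix(X_q); X_s <- as.matrix(X_s); A <- ag_val(A)
  if (ncol(A) != nrow(X_s))
    stop("attention columns (", ncol(A), ") must equal support rows (", nrow(X_s), ")")
  if (ncol(X_q) != params$d || ncol(X_s) != params$d)
    stop("feature width must equal d = ", params$d)
  ag_val(.pa_apply(X_q, A, X_s, params))
}

# residual conv block: x + zeroconv(gelu(conv(LN(x))))
.res_block_params <- function(w, prefix) {
  p <- list()
  p[[paste0(prefix, "_c1_w")]] <- ag_param(init_conv_w(w, w, 1L))
  p[[paste0(prefix, "_c1_b")]] <- ag_param(numeric(w))
  p[[paste0(prefix, "_c2_w")]] <- ag_param(matrix(0, w, w))
  p[[paste0(prefix, "_c2_b")]] <- ag_param(numeric(w))
  p
}

.res_block_apply <- function(P, prefix, x) {
  u <- ag_layernorm(x)
  u <- ag_conv2d(u, P[[paste0(prefix, "_c1_w")]], P[[paste0(prefix, "_c1_b")]], 1L)
  u <- ag_gelu(u)
  u <- ag_conv2d(u, P[[paste0(prefix, "_c2_w")]], P[[paste0(prefix, "_c2_b")]], 1L)
  ag_add(x, u)
}

#' Decoder parameters
#'
#' Stage channel widths mirror the encoder stage widths (stride 32 uses the
#' stage-4 width and so on down to the stem width at stride 2).
#'
#' @param config the shared [encoder_config()] of the segmentation/support
#'   encoders.
#' @return named list of autodiff parameter leaves plus the two
#'   provided-attention parameter sets for strides 16 and 8.
#' @export
decoder_params <- function(config) {
  w <- config$stage_widths
  ws <- config$stem_width
  P <- list()
  # stage 1 @32: provided attention + residual block
  pa1 <- provided_attention_params(w[4])
  P$pa1_W <- pa1$W_p; P$pa1_b <- pa1$b_p
  P <- c(P, .res_block_params(w[4], "st1"))
  # stage 2 @16; skip-fusion projections start as the identity so the
  # decoder sees multi-scale detail from the first step (they are plain skip
  # projections, not inner residual last layers, which stay zero-initialized)
  P$st2_up_w <- ag_param(init_convt_w(w[3], w[4], 3L)); P$st2_up_b <- ag_param(numeric(w[3]))
  P$st2_fuse_w <- ag_param(diag(w[3])); P$st2_fuse_b <- ag_param(numeric(w[3]))
  pa2 <- provided_attention_params(w[3])
  P$pa2_W <- pa2$W_p; P$pa2_b <- pa2$b_p
  P <- c(P, .res_block_params(w[3], "st2"))
  # stage 3 @8
  P$st3_up_w <- ag_param(init_convt_w(w[2], w[3], 3L)); P$st3_up_b <- ag_param(numeric(w[2]))
  P$st3_fuse_w <- ag_param(diag(w[2])); P$st3_fuse_b <- ag_param(numeric(w[2]))
  pa3 <- provided_attention_params(w[2])
  P$pa3_W <- pa3$W_p; P$pa3_b <- pa3$b_p
  P <- c(P, .res_block_params(w[2], "st3"))
  # stage 4 @4 and stage 5 @2: query skips only
  P$st4_up_w <- ag_param(init_convt_w(w[1], w[2], 3L)); P$st4_up_b <- ag_param(numeric(w[1]))
  P$st4_fuse_w <- ag_param(diag(w[1])); P$st4_fuse_b <- ag_param(numeric(w[1]))
  P <- c(P, .res_block_params(w[1], "st4"))
  P$st5_up_w <- ag_param(init_convt_w(ws, w[1], 3L)); P$st5_up_b <- ag_param(numeric(ws))
  P$st5_fuse_w <- ag_param(diag(ws)); P$st5_fuse_b <- ag_param(numeric(ws))
  P <- c(P, .res_block_params(ws, "st5"))
  # head: upsample stride 2 -> 1, then 1x1 sigmoid projector
  P$head_up_w <- ag_param(init_convt_w(ws, ws, 3L)); P$head_up_b <- ag_param(numeric(ws))
  P$head_proj_w <- ag_param(init_conv_w(1L, ws, 1L, rng_sd = 0.01))
  P$head_proj_b <- ag_param(numeric(1L))
  P
}

# PA fusion at one stage: D (Hq, Wq, d, 1) tensor, attention object, support
# skip level (H, W, d, S). Returns updated D.
.pa_stage <- function(D, Aobj, sup_level, W_p, b_p) {
  dd <- dim(ag_val(D))
  Xq <- ag_flatten_hw(D)
  Xs <- ag_flatten_hw(sup_level)
  pooled <- ag_matmul(as_ag(Aobj$A), Xs)
  upd <- ag_dense(pooled, ag_t(W_p), b_p)
  Xq2 <- ag_add(Xq, upd)
  ag_unflatten_hw(Xq2, dd[1], dd[2])
}

# Full decoder forward (autodiff). `pyr_*` are lists of ag tensors (levels by
# stride); attention objects carry ag tensors in $A during training.
.decode_forward <- function(P, pyr_seg, pyr_sup, A32, A16, A8) {
  D <- pyr_seg[["32"]]
  D <- .pa_stage(D, A32, pyr_sup[["32"]], P$pa1_W, P$pa1_b)
  D <- .res_block_apply(P, "st1", D)

  D <- ag_convt2d(D, P$st2_up_w, P$st2_up_b)
  skip <- ag_conv2d(pyr_seg[["16"]], P$st2_fuse_w, P$st2_fuse_b, 1L)
  D <- ag_add(D, skip)
  D <- .pa_stage(D, A16, pyr_sup[["16"]], P$pa2_W, P$pa2_b)
  D <- .res_block_apply(P, "st2", D)

  D <- ag_convt2d(D, P$st3_up_w, P$st3_up_b)
  skip <- ag_conv2d(pyr_seg[["8"]], P$st3_fuse_w, P$st3_fuse_b, 1L)
  D <- ag_add(D, skip)
  D <- .pa_stage(D, A8, pyr_sup[["8"]], P$pa3_W, P$pa3_b)
  D <- .res_block_apply(P, "st3", D)

  D <- ag_convt2d(D, P$st4_up_w, P$st4_up_b)
  skip <- ag_conv2d(pyr_seg[["4"]], P$st4_fuse_w, P$st4_fuse_b, 1L)
  D <- ag_add(D, skip)
  D <- .res_block_apply(P, "st4", D)

  D <- ag_convt2d(D, P$st5_up_w, P$st5_up_b)
  skip <- ag_conv2d(pyr_seg[["2"]], P$st5_fuse_w, P$st5_fuse_b, 1L)
  D <- ag_add(D, skip)
  D <- .res_block_apply(P, "st5", D)

  D <- ag_convt2d(D, P$head_up_w, P$head_up_b)
  D <- ag_gelu(D)
  logits <- ag_conv2d(D, P$head_proj_w, P$head_proj_b, 1L)
  logits
}
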