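# ---------------------------------------------------------------------------
# Cross Attention Mapper and Attention Upsampler.
#
# The coarse attention map is a one-head attention between the query's
# coarsest (stride-32) features and the support set's coarsest features from
# the EMA encoder:
#     A_i = softmax(X_i^q W_Q W_K' [X^s; t^s]' / (delta * T))[, 1:SHW]
# with delta = 0.1 d, a learnable positive temperature T, and n_reg learnable
# registry tokens t^s whose (discarded) softmax mass lets a query location
# attend "nowhere in the support set". Support masks never enter this path.
#
# Flattening convention (used everywhere): spatial positions are row-major
# (h outer, w inner), support examples concatenated in given order.
# ---------------------------------------------------------------------------

#' Cross-attention mapper parameters
#'
#' @param d feature channel count of the coarsest attention-encoder level.
#' @param n_registry number of registry tokens (0 disables them).
#' @return parameter list with `W_Q`, `W_K` (d x d), `tau` (temperature is
#'   `exp(tau)`, so it is positive by construction) and `registry`
#'   (n_registry x d).
#' @export
cross_attention_params <- function(d, n_registry = 4L) {
  structure(list(
    # near-identity init: the bilinear form starts as a plain feature
    # similarity, so the coarse map is informative from the first step
    W_Q = ag_param(diag(d) + 0.02 * matrix(stats::rnorm(d * d), d, d)),
    W_K = ag_param(diag(d) + 0.02 * matrix(stats::rnorm(d * d), d, d)),
    tau = ag_param(0),
    registry = if (n_registry > 0L)
      ag_param(matrix(stats::rnorm(n_registry * d), n_registry, d)) else NULL,
    d = as.integer(d), n_registry = as.integer(n_registry)
  ), class = "cross_attention_params")
}

# core (autodiff) computation; Xq (HW x d), Xs (SHW x d) tensors or arrays
.attn_coarse <- function(params, Xq, Xs, S, H, W) {
  Xq <- as_ag(Xq); Xs <- as_ag(Xs)
  d <- params$d
  n_reg <- params$n_registry
  delta <- 0.1 * d                       # recomputed from d, never stored
  keysrc <- if (n_reg > 0L) ag_rbind(Xs, params$registry) else Xs
  Q <- ag_matmul(Xq, params$W_Q)
  K <- ag_matmul(keysrc, params$W_K)
  Tpos <- ag_exp(params$tau)
  logits <- ag_div(ag_smul(ag_matmul(Q, ag_t(K)), 1 / delta), Tpos)
  P <- ag_softmax_rows(logits)
  n_sup <- S * H * W
  if (n_reg > 0L) {
    A <- ag_node(P$val[, seq_len(n_sup), drop = FALSE], list(P), function(g) {
      gg <- matrix(0, nrow(P$val), ncol(P$val))
      gg[, seq_len(n_sup)] <- g
      list(gg)
    })
    reg_mass <- 1 - rowSums(ag_val(A))
  } else {
    A <- P
    reg_mass <- numeric(nrow(ag_val(P)))
  }
  structure(list(A = A, registry_mass = reg_mass,
                 mass = rowSums(ag_val(A)),
                 S = S, H = H, W = W, Hq = H, Wq = W,
                 flattening = "row-major (h outer, w inner); support examples in order"),
            class = "coarse_attention")
}

#' Compute the coarse cross-attention map
#'
#' @param params a [cross_attention_params()] object.
#' @param query_feats (H*W) x d matrix of flattened query features.
#' @param support_feats (S*H*W) x d matrix of flattened support features.
#' @param S,H,W geometry of the support grid; defaults assume a single
#'   square support example when omitted.
#' @return a `coarse_attention` object: `A` ((HW) x (SHW), nonnegative, row
#'   sums + registry mass = 1), `registry_mass`, `mass`, and the geometry.
#' @export
compute_coarse_attention <- function(params, query_feats, support_feats,
                                     S = NULL, H = NULL, W = NULL) {
  query_feats <- as.matrix(query_feats); support_feats <- as.matrix(support_feats)
  if (ncol(query_feats) != params$d || ncol(support_feats) != params$d)
    stop("feature dimensionality does not match attention parameters (d = ",
         params$d, ")")
  if (!all(is.finite(query_feats)) || !all(is.finite(support_feats)))
    stop("non-finite features passed to the attention mapper")
  if (is.null(H)) H <- as.integer(round(sqrt(nrow(query_feats))))
  if (is.null(W)) W <- as.integer(nrow(query_feats) / H)
  if (is.null(S)) S <- as.integer(nrow(support_feats) / (H * W))
  if (S * H * W != nrow(support_feats))
    stop("support feature rows (", nrow(support_feats), ") not equal to S*H*W")
  res <- .attn_coarse(params, query_feats, support_feats, S, H, W)
  res$A <- ag_val(res$A)
  res
}

#' Top-K support locations of one attention row
#'
#' Indices of the K largest weights, sorted decreasingly; ties are broken by
#' the lower flattened support index for determinism.
#'
#' @param row numeric vector of attention weights.
#' @param K number of locations (clamped to `length(row)`).
#' @return integer indices.
#' @export
topk_select <- function(row, K) {
  stopifnot(K >= 1)
  K <- min(K, length(row))
  order(-row, seq_along(row))[seq_len(K)]
}

#' Rescale attention rows to a target mass
#'
#' Row i is scaled so that its sum equals `target_mass[i]`; zero rows are
#' left untouched (no division by zero).
#'
#' @param A attention matrix.
#' @param target_mass nonnegative vector, one entry per row.
#' @return rescaled matrix.
#' @export
renormalize_to_mass <- function(A, target_mass) {
  target_mass <- as.vector(ag_val(target_mass))
  if (any(target_mass < 0)) stop("attention mass must be nonnegative")
  if (length(target_mass) != nrow(ag_val(A)))
    stop("target mass length must equal the number of rows")
  ag_val(ag_safe_rowscale(as_ag(A), ag_const(target_mass)))
}

#' Attention upsampler parameters
#'
#' @param d channel count of the attention-encoder level the upsampler
#'   refines at (FFN input is 1 + 2d: attention value, query feature vector,
#'   support feature vector).
#' @param c_init initial nearest/bilinear mixing coefficient in (0, 1);
#'   parametrized through a logistic transform so it stays in `[0, 1]`.
#' @return parameter list; the refinement FFN's last layer is zero-initialized
#'   so refinement starts as the identity.
#' @export
upsampler_params <- function(d, c_init = 0.5) {
  stopifnot(c_init > 0, c_init < 1)
  structure(list(
    u = ag_param(log(c_init / (1 - c_init))),
    ffn_w1 = ag_param(init_dense_w(d, 1L + 2L * d)),
    ffn_b1 = ag_param(numeric(d)),
    ffn_w2 = ag_param(matrix(0, 1L, d)),
    ffn_b2 = ag_param(0),
    d = as.integer(d)
  ), class = "upsampler_params")
}

# Core upsampler on autodiff tensors.
#   Aobj: coarse_attention / upsampled_attention (A may be ag or plain)
#   qfeat: ((2Hq)(2Wq)) x d tensor, sfeat: (S(2H)(2W)) x d tensor
.attn_upsample <- function(Aobj, params, qfeat, sfeat, K) {
  A <- as_ag(Aobj$A)
  qfeat <- as_ag(qfeat); sfeat <- as_ag(sfeat)
  S <- Aobj$S; H <- Aobj$H; W <- Aobj$W
  Hq <- Aobj$Hq; Wq <- Aobj$Wq
  rows <- Hq * Wq
  c_mix <- ag_sigmoid(params$u)

  # step 1: per-row attention mass
  mass <- ag_rowsums(A)

  # step 2: upsample support axes; columns ordered w fastest, h, s
  A4 <- ag_reshape(A, c(rows, W, H, S))
  A4 <- ag_axis_upsample_mix(A4, 2L, c_mix, W)
  A4 <- ag_axis_upsample_mix(A4, 3L, c_mix, H)

  # step 3: upsample query axes (rows ordered w fastest then h)
  A6 <- ag_reshape(A4, c(Wq, Hq, 2L * W, 2L * H, S))
  A6 <- ag_axis_upsample_mix(A6, 1L, c_mix, Wq)
  A6 <- ag_axis_upsample_mix(A6, 2L, c_mix, Hq)
  rows2 <- 4L * rows
  ncol2 <- S * 4L * H * W
  Aup <- ag_reshape(A6, c(rows2, ncol2))

  # step 4: upsample mass on the query grid and renormalize rows to it
  Mq <- ag_reshape(mass, c(Wq, Hq))
  Mq <- ag_axis_upsample_mix(Mq, 1L, c_mix, Wq)
  Mq <- ag_axis_upsample_mix(Mq, 2L, c_mix, Hq)
  mass_up <- ag_reshape(Mq, c(rows2))
  Aup <- ag_safe_rowscale(Aup, mass_up)

  # step 5: refine top-K entries per row with the FFN; others keep their
  # interpolated values
  if (K > ncol2) {
    warning("top-K (", K, ") exceeds support locations (", ncol2, "); clamped")
    K <- ncol2
  }
  Av <- ag_val(Aup)
  sel <- vapply(seq_len(rows2), function(i) topk_select(Av[i, ], K), integer(K))
  col_idx <- as.vector(sel)                      # K entries per row, rows stacked
  row_idx <- rep(seq_len(rows2), each = K)
  flat <- row_idx + rows2 * (col_idx - 1L)
  v <- ag_gather(Aup, flat)
  qg <- ag_gather_rows(qfeat, row_idx)
  sg <- ag_gather_rows(sfeat, col_idx)
  Xf <- ag_cbind(ag_reshape(v, c(length(flat), 1L)), qg, sg)
  hmid <- ag_gelu(ag_dense(Xf, params$ffn_w1, params$ffn_b1))
  y <- ag_dense(hmid, params$ffn_w2, params$ffn_b2)
  factor <- ag_add(ag_const(1), ag_elu(y))
  refined <- ag_mul(v, ag_reshape(factor, c(length(flat))))
  Aref <- ag_index_put(Aup, flat, refined)

  # step 6: renormalize to the upsampled mass again
  Afin <- ag_safe_rowscale(Aref, mass_up)

  structure(list(A = Afin, mass = as.vector(ag_val(mass_up)),
                 S = S, H = 2L * H, W = 2L * W, Hq = 2L * Hq, Wq = 2L * Wq,
                 K = K,
                 flattening = Aobj$flattening),
            class = "upsampled_attention")
}

#' Upsample and refine an attention map
#'
#' Implements the attention upsampler: (1) compute the per-row attention
#' mass; (2) interpolate columns 2x per support example with the learnable
#' nearest/bilinear mix; (3) likewise interpolate the query rows; (4)
#' upsample the mass on the query grid and rescale each row to it; (5)
#' refine the top-K support locations per row as
#' `A_ij <- A_ij * (1 + ELU(y_FFN))`; (6) rescale rows to the mass again.
#'
#' @param A a `coarse_attention` or `upsampled_attention` object.
#' @param params an [upsampler_params()] object.
#' @param query_feats_next flattened query features at the doubled query
#'   resolution (from the attention mapper encoder).
#' @param support_feats_next flattened support features at the doubled
#'   support resolution (from the EMA encoder).
#' @param K number of refined support locations per query location.
#' @return an `upsampled_attention` object.
#' @export
upsample_attention <- function(A, params, query_feats_next, support_feats_next, K) {
  res <- .attn_upsample(A, params, as.matrix(query_feats_next),
                        as.matrix(support_feats_next), K)
  res$A <- ag_val(res$A)
  res
}
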