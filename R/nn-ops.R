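# ---------------------------------------------------------------------------
# Neural-network primitives on 4D (H, W, C, N) arrays, built on the autodiff
# tape and the compiled im2col/col2im kernels. Weight layouts:
#   conv2d       : Wm (Cout, k*k*Cin), rows of im2col ordered kh, kw, c
#   conv_t2d     : Wt (k*k*Cout, Cin)
#   depthwise 3x3: Wd (9, C)
# Biases are per-output-channel vectors.
# ---------------------------------------------------------------------------

ag_conv2d <- function(x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xd <- dim(x$val)
  H <- xd[1]; W <- xd[2]; C <- xd[3]; N <- xd[4]
  Hout <- (H + 2L * pad - k) %/% stride + 1L
  Wout <- (W + 2L * pad - k) %/% stride + 1L
  Cout <- nrow(w$val)
  cols <- cpp_im2col_batch(x$val, H, W, C, N, k, stride, pad)  # (kkC, P*N)
  y <- w$val %*% cols + as.vector(b$val)          # bias recycles down rows
  out <- aperm(array(t(y), c(Hout, Wout, N, Cout)), c(1L, 2L, 4L, 3L))
  ag_node(out, list(x, w, b), function(g) {
    gm <- t(matrix(aperm(g, c(1L, 2L, 4L, 3L)), Hout * Wout * N, Cout))
    dw <- gm %*% t(cols)
    db <- rowSums(gm)
    dcols <- crossprod(w$val, gm)
    dx <- array(cpp_col2im_batch(dcols, H, W, C, N, k, stride, pad), xd)
    list(dx, dw, db)
  })
}

ag_dwconv2d <- function(x, w, b) {
  # depthwise 3x3, stride 1, pad 1; w is (9, C)
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xd <- dim(x$val)
  out <- array(cpp_dwconv_fwd(x$val, w$val, as.vector(b$val),
                              xd[1], xd[2], xd[3], xd[4]), xd)
  ag_node(out, list(x, w, b), function(g) {
    r <- cpp_dwconv_bwd(x$val, w$val, g, xd[1], xd[2], xd[3], xd[4])
    list(array(r$dx, xd), r$dw, as.vector(r$db))
  })
}

ag_convt2d <- function(x, w, b, k = 3L, stride = 2L, pad = 1L, opad = 1L) {
  # transposed convolution (backward-data of a k/stride/pad convolution);
  # w is (k*k*Cout, Cin)
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xd <- dim(x$val)
  H <- xd[1]; W <- xd[2]; Cin <- xd[3]; N <- xd[4]
  Hout <- (H - 1L) * stride - 2L * pad + k + opad
  Wout <- (W - 1L) * stride - 2L * pad + k + opad
  Cout <- nrow(w$val) %/% (k * k)
  xm <- t(matrix(aperm(x$val, c(1L, 2L, 4L, 3L)), H * W * N, Cin))  # (Cin, P*N)
  cols <- w$val %*% xm                              # (kkCout, P*N)
  yv <- cpp_col2im_batch(cols, Hout, Wout, Cout, N, k, stride, pad)
  out <- array(yv, c(Hout, Wout, Cout, N)) +
    rep(as.vector(b$val), each = Hout * Wout) # recycles over (H,W,C), then N
  ag_node(out, list(x, w, b), function(g) {
    db <- colSums(matrix(aperm(g, c(1L, 2L, 4L, 3L)), Hout * Wout * N, Cout))
    dcols <- cpp_im2col_batch(g, Hout, Wout, Cout, N, k, stride, pad)
    dw <- dcols %*% t(xm)
    dxm <- crossprod(w$val, dcols)                  # (Cin, P*N)
    dx <- aperm(array(t(dxm), c(H, W, N, Cin)), c(1L, 2L, 4L, 3L))
    list(dx, dw, db)
  })
}

# stable binary cross-entropy on logits, mean over all elements
ag_bce_logits <- function(logits, target) {
  logits <- as_ag(logits)
  z <- logits$val; t <- ag_val(target)
  n <- length(z)
  val <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  ag_node(val, list(logits), function(g)
    list(.g_as(as.numeric(g) * (p - t) / n, logits$val)))
}

# ------------------------- interpolation matrices ---------------------------

#' 2x axis-upsampling matrix
#'
#' Returns the (2n x n) linear map that doubles a length-n axis by
#' nearest-neighbour or bilinear interpolation (half-pixel centre
#' convention, edge-clamped).
#'
#' @param n input axis length.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a dense 2n x n matrix.
#' @keywords internal
interp_matrix <- function(n, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  m <- 2L * n
  M <- matrix(0, m, n)
  for (i in seq_len(m)) {
    if (method == "nearest") {
      src <- (i - 1L) %/% 2L + 1L
      M[i, src] <- 1
    } else {
      pos <- (i - 0.5) / 2 - 0.5          # 0-based source coordinate
      lo <- floor(pos)
      whi <- pos - lo
      lo_i <- min(max(lo, 0), n - 1) + 1
      hi_i <- min(max(lo + 1, 0), n - 1) + 1
      M[i, lo_i] <- M[i, lo_i] + (1 - whi)
      M[i, hi_i] <- M[i, hi_i] + whi
    }
  }
  M
}

# apply matrix M (m x n) along axis `axis` (of length n) of tensor x
ag_axis_matmul <- function(x, M, axis) {
  x <- as_ag(x)
  d <- dim(x$val)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  xp <- ag_aperm(x, perm)
  xm <- ag_reshape(xp, c(d[axis], prod(d[-axis])))
  ym <- ag_matmul(ag_const(M), xm)
  newd <- d; newd[axis] <- nrow(M)
  ya <- ag_reshape(ym, c(nrow(M), d[perm[-1]]))
  ag_aperm(ya, order(perm))
}

# learnable nearest/bilinear mix: c*NN + (1-c)*bilinear along one axis
ag_axis_upsample_mix <- function(x, axis, c_mix, n) {
  Mnn <- interp_matrix(n, "nearest")
  Mli <- interp_matrix(n, "bilinear")
  one_minus <- ag_sub(ag_const(1), c_mix)
  ag_add(ag_mul(ag_axis_matmul(x, Mnn, axis), c_mix),
         ag_mul(ag_axis_matmul(x, Mli, axis), one_minus))
}

# --------------------------- flattening helpers -----------------------------

# (H, W, C, N) -> (N*H*W, C) with row-major (h outer, w inner) per sample,
# samples concatenated in order. Single matrix op per sample.
ag_flatten_hw <- function(x) {
  x <- as_ag(x)
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- ag_aperm(x, c(2L, 1L, 4L, 3L))      # (W, H, N, C): w fastest, then h, n
  ag_reshape(xp, c(W * H * N, C))
}

# inverse: (H*W, C) matrix -> (H, W, C, 1) array
ag_unflatten_hw <- function(x, H, W) {
  x <- as_ag(x)
  C <- ncol(x$val)
  xa <- ag_reshape(x, c(W, H, 1L, C))
  ag_aperm(xa, c(2L, 1L, 4L, 3L))
}

flatten_hw <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2L, 1L, 4L, 3L)), nrow = d[1] * d[2] * d[4], ncol = d[3])
}

# ------------------------------ initializers --------------------------------

init_conv_w <- function(cout, cin, k, rng_sd = NULL) {
  fan_in <- k * k * cin
  sd <- rng_sd %||% sqrt(2 / fan_in)
  matrix(stats::rnorm(cout * fan_in, sd = sd), cout, fan_in)
}

init_convt_w <- function(cout, cin, k) {
  fan_in <- k * k * cin
  matrix(stats::rnorm(k * k * cout * cin, sd = sqrt(2 / fan_in)), k * k * cout, cin)
}

init_dense_w <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}
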