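# Independent oracles used by the unit tests. These deliberately avoid the
# package's vectorized/graph code paths: scalar loops and direct formula
# evaluation only.

ns <- asNamespace("icseg")

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Brute-force evaluation of the coarse attention softmax: one scalar loop
# per logit, softmax by hand, truncation to the support entries.
oracle_coarse_attention <- function(WQ, WK, tau, registry, Xq, Xs) {
  d <- ncol(Xq)
  delta <- 0.1 * d
  Temp <- exp(tau)
  keys <- rbind(Xs, registry)
  nq <- nrow(Xq); nk <- nrow(keys)
  A_full <- matrix(0, nq, nk)
  for (i in seq_len(nq)) {
    logits <- numeric(nk)
    for (j in seq_len(nk)) {
      q <- as.numeric(Xq[i, ] %*% WQ)
      k <- as.numeric(keys[j, ] %*% WK)
      logits[j] <- sum(q * k) / (delta * Temp)
    }
    e <- exp(logits - max(logits))
    A_full[i, ] <- e / sum(e)
  }
  list(A = A_full[, seq_len(nrow(Xs)), drop = FALSE],
       registry_mass = rowSums(A_full[, -seq_len(nrow(Xs)), drop = FALSE]))
}

# 2x interpolation weight of output index i (1-based) onto input index j
# for a length-n axis; mirrors the half-pixel-centre convention.
.interp_w <- function(n, method) {
  M <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    if (method == "nearest") {
      M[i, (i - 1) %/% 2 + 1] <- 1
    } else {
      pos <- (i - 0.5) / 2 - 0.5
      lo <- floor(pos); whi <- pos - lo
      lo_i <- min(max(lo, 0), n - 1) + 1
      hi_i <- min(max(lo + 1, 0), n - 1) + 1
      M[i, lo_i] <- M[i, lo_i] + 1 - whi
      M[i, hi_i] <- M[i, hi_i] + whi
    }
  }
  M
}

# Dense attention-upsampling oracle: explicit index arithmetic, no sparse
# top-K shortcut. Assumes a zero-initialized refinement FFN (factor 1), so
# steps 5-6 reduce to the renormalization of step 4.
oracle_dense_upsample <- function(A, S, H, W, Hq, Wq, cmix) {
  mix <- function(n) cmix * .interp_w(n, "nearest") + (1 - cmix) * .interp_w(n, "bilinear")
  Mh <- mix(H); Mw <- mix(W); Mhq <- mix(Hq); Mwq <- mix(Wq)
  rows2 <- 4 * Hq * Wq; cols2 <- S * 4 * H * W
  out <- matrix(0, rows2, cols2)
  rix <- function(h, w, Wax) (h - 1) * Wax + w
  for (hq2 in seq_len(2 * Hq)) for (wq2 in seq_len(2 * Wq)) {
    r2 <- rix(hq2, wq2, 2 * Wq)
    for (s in seq_len(S)) for (h2 in seq_len(2 * H)) for (w2 in seq_len(2 * W)) {
      c2 <- (s - 1) * 4 * H * W + rix(h2, w2, 2 * W)
      acc <- 0
      for (hq in seq_len(Hq)) for (wq in seq_len(Wq)) {
        whq <- Mhq[hq2, hq]; wwq <- Mwq[wq2, wq]
        if (whq == 0 || wwq == 0) next
        r1 <- rix(hq, wq, Wq)
        for (h in seq_len(H)) for (w in seq_len(W)) {
          wh <- Mh[h2, h]; ww <- Mw[w2, w]
          if (wh == 0 || ww == 0) next
          c1 <- (s - 1) * H * W + rix(h, w, W)
          acc <- acc + whq * wwq * wh * ww * A[r1, c1]
        }
      }
      out[r2, c2] <- acc
    }
  }
  # upsampled mass on the query grid
  mass <- rowSums(A)
  mass_up <- numeric(rows2)
  for (hq2 in seq_len(2 * Hq)) for (wq2 in seq_len(2 * Wq)) {
    acc <- 0
    for (hq in seq_len(Hq)) for (wq in seq_len(Wq))
      acc <- acc + Mhq[hq2, hq] * Mwq[wq2, wq] * mass[rix(hq, wq, Wq)]
    mass_up[rix(hq2, wq2, 2 * Wq)] <- acc
  }
  rs <- rowSums(out)
  for (r in seq_len(rows2)) if (rs[r] > 0) out[r, ] <- out[r, ] * mass_up[r] / rs[r]
  list(A = out, mass = mass_up)
}

# random small episode helper (plain noise scenes; no task structure needed)
random_episode <- function(n = 64L, S = 2L) {
  mk <- function() matrix(runif(n * n), n, n)
  msk <- function() {
    m <- matrix(0, n, n)
    m[seq(n %/% 4, n %/% 2), seq(n %/% 4, n %/% 2)] <- 1
    m
  }
  list(query_image = mk(), query_mask = msk(),
       support_images = replicate(S, mk(), simplify = FALSE),
       support_masks = replicate(S, msk(), simplify = FALSE),
       task_id = "random")
}
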