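test_that("provided-attention block matches an explicit per-row loop", {
  set.seed(51)
  rows <- 4L; srows <- 8L; d <- 3L
  Xq <- matrix(rnorm(rows * d), rows, d)
  Xs <- matrix(rnorm(srows * d), srows, d)
  A <- matrix(runif(rows * srows), rows, srows)
  p <- provided_attention_params(d)
  p$W_p$val <- matrix(rnorm(d * d), d, d)
  p$b_p$val <- rnorm(d)
  got <- provided_attention_apply(Xq, A, Xs, p)
  want <- Xq
  for (i in seq_len(rows))
    want[i, ] <- Xq[i, ] + as.numeric(A[i, ] %*% Xs %*% p$W_p$val) + p$b_p$val
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("provided attention degenerates correctly", {
  d <- 3L
  p <- provided_attention_params(d)           # zero-init: identity block
  Xq <- matrix(rnorm(6), 2, d); Xs <- matrix(rnorm(12), 4, d)
  A <- matrix(runif(8), 2, 4)
  expect_equal(provided_attention_apply(Xq, A, Xs, p), Xq)
  # identity projection + one-hot attention row adds the selected support row
  p$W_p$val <- diag(d)
  A1 <- matrix(0, 2, 4); A1[1, 3] <- 1
  got <- provided_attention_apply(Xq, A1, Xs, p)
  expect_equal(got[1, ], Xq[1, ] + Xs[3, ])
  expect_equal(got[2, ], Xq[2, ])
  expect_error(provided_attention_apply(Xq, matrix(0, 2, 5), Xs, p),
               "support rows")
})

test_that("prediction has the output contract and is deterministic", {
  set.seed(52)
  model <- icseg_model("tiny", seed = 3)
  ep <- random_episode(64L, 2L)
  p1 <- predict_episode(model, ep)
  expect_equal(dim(p1$mask), c(64L, 64L))
  expect_true(all(p1$mask > 0 & p1$mask < 1))
  p2 <- predict_episode(model, ep)
  expect_identical(p1$mask, p2$mask)
})

test_that("the final mask is invariant to support permutation", {
  set.seed(53)
  model <- icseg_model("tiny", seed = 4)
  ep <- random_episode(64L, 3L)
  perm <- c(2L, 3L, 1L)
  ep2 <- ep
  ep2$support_images <- ep$support_images[perm]
  ep2$support_masks <- ep$support_masks[perm]
  m1 <- predict_episode(model, ep)$mask
  m2 <- predict_episode(model, ep2)$mask
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("residual stages contribute exactly zero at initialization", {
  # with zero-initialized last layers the decoder output must be unchanged
  # when every inner residual update is removed; probe via the head on a
  # fresh model: perturbing a residual last layer's *input* path changes
  # nothing at init because the layer multiplies by zero.
  set.seed(54)
  model <- icseg_model("tiny", seed = 6)
  ep <- random_episode(64L, 2L)
  base <- predict_episode(model, ep)$mask
  m2 <- icseg_model("tiny", seed = 6)
  # perturb the first (non-final) layer inside every residual block
  for (nm in names(m2$dec)) {
    if (grepl("_c1_w$", nm)) m2$dec[[nm]]$val <- m2$dec[[nm]]$val + 0.1
  }
  pert <- predict_episode(m2, ep)$mask
  expect_equal(base, pert, tolerance = 1e-12)
})

test_that("gradients reach every trainable component after a training step", {
  # at exact initialization the zero-initialized residual last layers block
  # the inner paths by design; after one optimizer step they are nonzero and
  # gradients must reach every component
  set.seed(55)
  model <- icseg_model("tiny", seed = 7)
  ep <- random_episode(64L, 2L)
  params <- collect_params(model)
  opt <- ns$adamw_init(params)
  for (it in 1:3) {
    ns$ag_zero_grad(params)
    fw <- ns$model_forward(model, ep, K_base = 4L)
    loss <- ns$.ag_loss(fw$logits, ep$query_mask, loss_config())
    ns$ag_backward(loss)
    if (it < 3) opt <- ns$adamw_step(opt, params, 1e-3, 0)
  }
  groups <- c("attn.W_Q", "attn.W_K", "attn.tau", "attn.registry",
              "ups16.u", "ups16.ffn_w1", "ups8.ffn_w1",
              "dec.pa1_W", "dec.pa1_b", "dec.pa2_W", "dec.pa3_W",
              "map.stem1_w", "sup.stem1_w", "seg.stem1_w")
  for (g in groups) {
    expect_false(is.null(params[[g]]$grad), label = paste("grad missing:", g))
    expect_gt(max(abs(params[[g]]$grad)), 0, label = paste("zero grad:", g))
  }
  # refinement FFN last layers receive gradients as well
  expect_false(is.null(params[["ups16.ffn_w2"]]$grad))
  expect_false(is.null(params[["ups8.ffn_w2"]]$grad))
})

test_that("zeroing the attention maps severs all support-mask influence", {
  set.seed(56)
  model <- icseg_model("tiny", seed = 8)
  # make the decoder's provided-attention projections non-trivial so masks
  # genuinely matter when attention is active
  for (nm in c("pa1_W", "pa2_W", "pa3_W"))
    model$dec[[nm]]$val <- model$dec[[nm]]$val + 0.2 * diag(nrow(model$dec[[nm]]$val))
  ep <- random_episode(64L, 2L)
  ep_flip <- ep
  ep_flip$support_masks <- lapply(ep$support_masks, function(m) 1 - m)
  # with active attention, flipping the support masks changes the output
  m_a <- predict_episode(model, ep)$mask
  m_b <- predict_episode(model, ep_flip)$mask
  expect_gt(max(abs(m_a - m_b)), 1e-8)
  # with the attention maps forced to zero, the decoder output is identical
  # for arbitrary support masks: the support-set encoder is the only mask
  # pathway and it is modulated solely by A
  decode_zeroA <- function(ep) {
    H <- nrow(ep$query_image)
    qx <- ns$ag_const(array(ep$query_image, c(H, H, 1L, 1L)))
    S <- length(ep$support_images)
    sx <- array(0, c(H, H, 2L, S))
    for (s in seq_len(S)) {
      sx[, , 1, s] <- ep$support_images[[s]]
      sx[, , 2, s] <- ep$support_masks[[s]]
    }
    seg <- ns$encoder_forward(model$enc_seg, qx)$levels
    sup <- ns$encoder_forward(model$enc_sup, ns$ag_const(sx))$levels
    zA <- function(rows, cols, H, W, Hq, Wq)
      structure(list(A = matrix(0, rows, cols), S = S, H = H, W = W,
                     Hq = Hq, Wq = Wq), class = "coarse_attention")
    g <- H / 32L
    A32 <- zA(g * g, S * g * g, g, g, g, g)
    A16 <- zA(4 * g * g, S * 4 * g * g, 2 * g, 2 * g, 2 * g, 2 * g)
    A8 <- zA(16 * g * g, S * 16 * g * g, 4 * g, 4 * g, 4 * g, 4 * g)
    ns$ag_val(ns$.decode_forward(model$dec, seg, sup, A32, A16, A8))
  }
  expect_identical(decode_zeroA(ep), decode_zeroA(ep_flip))
})
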