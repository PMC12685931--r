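make_attn_params <- function(d, n_reg = 0L, WQ = NULL, WK = NULL, tau = 0,
                             registry = NULL) {
  p <- cross_attention_params(d, n_reg)
  if (!is.null(WQ)) p$W_Q$val <- WQ
  if (!is.null(WK)) p$W_K$val <- WK
  p$tau$val <- tau
  if (!is.null(registry)) p$registry$val <- registry
  p
}

test_that("coarse attention matches a scalar-loop evaluation", {
  set.seed(31)
  d <- 3L; S <- 2L; H <- 2L; W <- 2L
  Xq <- matrix(rnorm(H * W * d), H * W, d)
  Xs <- matrix(rnorm(S * H * W * d), S * H * W, d)
  WQ <- matrix(rnorm(d * d), d, d); WK <- matrix(rnorm(d * d), d, d)
  reg <- matrix(rnorm(2 * d), 2, d)
  p <- make_attn_params(d, 2L, WQ, WK, tau = 0.3, registry = reg)
  res <- compute_coarse_attention(p, Xq, Xs, S = S, H = H, W = W)
  orc <- oracle_coarse_attention(WQ, WK, 0.3, reg, Xq, Xs)
  expect_equal(res$A, orc$A, tolerance = 1e-6)
  expect_equal(res$registry_mass, orc$registry_mass, tolerance = 1e-6)
  # row mass + registry mass = 1
  expect_equal(rowSums(res$A) + res$registry_mass, rep(1, H * W),
               tolerance = 1e-5)
})

test_that("without registry tokens every row sums to one", {
  set.seed(32)
  d <- 4L
  p <- make_attn_params(d, 0L)
  p$W_Q$val <- ns$init_dense_w(d, d); p$W_K$val <- ns$init_dense_w(d, d)
  Xq <- matrix(rnorm(16 * d), 16, d); Xs <- matrix(rnorm(32 * d), 32, d)
  res <- compute_coarse_attention(p, Xq, Xs, S = 2L, H = 4L, W = 4L)
  expect_equal(rowSums(res$A), rep(1, 16), tolerance = 1e-6)
  expect_true(all(res$A >= 0))
})

test_that("a registry token with the support's logit splits the mass evenly", {
  # S=1, H=W=1, d=2, identity projections, T=1: support key equals the token
  d <- 2L
  xs <- matrix(c(1, 0.5), 1, d)
  p <- make_attn_params(d, 1L, diag(d), diag(d), tau = 0, registry = xs)
  res <- compute_coarse_attention(p, matrix(c(0.3, -0.2), 1, d), xs,
                                  S = 1L, H = 1L, W = 1L)
  expect_equal(as.numeric(res$A), 0.5, tolerance = 1e-9)
  expect_equal(res$registry_mass, 0.5, tolerance = 1e-9)
})

test_that("attention depends on support images only, never on masks", {
  set.seed(33)
  model <- icseg_model("tiny", seed = 5)
  ep <- random_episode(64L, 2L)
  a1 <- predict_episode(model, ep, export_attention = TRUE)$stage_attention
  ep2 <- ep
  ep2$support_masks <- lapply(ep$support_masks, function(m) 1 - m)
  a2 <- predict_episode(model, ep2, export_attention = TRUE)$stage_attention
  expect_identical(a1$stride32$A, a2$stride32$A)
  expect_identical(a1$stride8$A, a2$stride8$A)
})

test_that("support permutation permutes column blocks and preserves registry mass", {
  set.seed(34)
  d <- 3L; S <- 3L; H <- 2L; W <- 2L
  Xq <- matrix(rnorm(H * W * d), H * W, d)
  Xs <- matrix(rnorm(S * H * W * d), S * H * W, d)
  p <- make_attn_params(d, 2L, matrix(rnorm(9), 3), matrix(rnorm(9), 3),
                        tau = 0, registry = matrix(rnorm(6), 2, d))
  res <- compute_coarse_attention(p, Xq, Xs, S = S, H = H, W = W)
  perm <- c(3L, 1L, 2L)
  blk <- function(s) ((s - 1) * H * W + 1):(s * H * W)
  Xs_p <- Xs[unlist(lapply(perm, blk)), ]
  res_p <- compute_coarse_attention(p, Xq, Xs_p, S = S, H = H, W = W)
  expect_equal(res_p$A, res$A[, unlist(lapply(perm, blk))], tolerance = 1e-12)
  expect_equal(res_p$registry_mass, res$registry_mass, tolerance = 1e-12)
})

test_that("raising a registry token's logit drains support mass monotonically", {
  set.seed(35)
  d <- 2L
  Xq <- matrix(rnorm(d), 1, d)
  Xs <- matrix(rnorm(2 * d), 2, d)
  masses <- vapply(c(0.5, 1, 2, 4), function(scale) {
    p <- make_attn_params(d, 1L, diag(d), diag(d), tau = 0,
                          registry = matrix(scale * c(1, 1), 1, d))
    # scale the token along a direction aligned with the query projection
    q <- Xq %*% diag(d)
    tok <- matrix(scale * q / sqrt(sum(q^2)), 1, d)
    p$registry$val <- tok
    sum(compute_coarse_attention(p, Xq, Xs, S = 1L, H = 1L, W = 2L)$A)
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
})

test_that("top-K selection matches a full sort and breaks ties low", {
  expect_equal(topk_select(c(0.1, 0.7, 0.2), 2), c(2L, 3L))
  expect_equal(topk_select(rep(0.5, 4), 2), c(1L, 2L))
  set.seed(36)
  row <- runif(50)
  expect_equal(topk_select(row, 5), order(row, decreasing = TRUE)[1:5])
})

test_that("row renormalization hits the target mass and guards zero rows", {
  # proportional scaling: [2, 2] with target mass 0.5 -> [0.25, 0.25]
  expect_equal(renormalize_to_mass(matrix(c(2, 2), 1), 0.5),
               matrix(c(0.25, 0.25), 1))
  expect_equal(sum(renormalize_to_mass(matrix(c(2, 2), 1), 0.5)), 0.5)
  expect_equal(renormalize_to_mass(matrix(0, 1, 3), 0.3), matrix(0, 1, 3))
  set.seed(37)
  A <- matrix(runif(40), 5, 8)
  tm <- runif(5)
  expect_equal(rowSums(renormalize_to_mass(A, tm)), tm, tolerance = 1e-6)
  expect_error(renormalize_to_mass(A, c(-1, 1, 1, 1, 1)), "nonnegative")
})

test_that("sparse upsampler with K = all and zero FFN matches the dense oracle", {
  set.seed(38)
  for (case in list(list(S = 1L, H = 2L, W = 2L), list(S = 2L, H = 4L, W = 3L))) {
    S <- case$S; H <- case$H; W <- case$W
    d <- 3L
    A <- matrix(runif(H * W * S * H * W), H * W, S * H * W)
    Aobj <- structure(list(A = A, S = S, H = H, W = W, Hq = H, Wq = W,
                           flattening = "row-major"), class = "coarse_attention")
    cmix <- 0.37
    up <- upsampler_params(d, c_init = cmix)     # FFN last layer zero-init
    qf <- matrix(rnorm(4 * H * W * d), 4 * H * W, d)
    sf <- matrix(rnorm(S * 4 * H * W * d), S * 4 * H * W, d)
    res <- upsample_attention(Aobj, up, qf, sf, K = S * 4L * H * W)
    orc <- oracle_dense_upsample(A, S, H, W, H, W, cmix)
    expect_equal(res$A, orc$A, tolerance = 1e-5)
    expect_equal(res$mass, orc$mass, tolerance = 1e-5)
  }
})

test_that("a uniform map stays uniform under interpolation with unit mass", {
  S <- 1L; H <- 2L; W <- 2L
  A <- matrix(1 / (S * H * W), H * W, S * H * W)
  Aobj <- structure(list(A = A, S = S, H = H, W = W, Hq = H, Wq = W),
                    class = "coarse_attention")
  up <- upsampler_params(2L, c_init = 0.999)  # essentially pure nearest
  up$u$val <- 30                               # c -> 1 exactly in double precision
  qf <- matrix(0, 16, 2); sf <- matrix(0, 16, 2)
  res <- upsample_attention(Aobj, up, qf, sf, K = 16L)
  expect_equal(res$A, matrix(1 / 16, 16, 16), tolerance = 1e-8)
  expect_equal(res$mass, rep(1, 16), tolerance = 1e-8)
})

test_that("upsampled row sums equal the interpolated mass even with active refinement", {
  set.seed(39)
  S <- 2L; H <- 2L; W <- 2L; d <- 3L
  A <- matrix(runif(32), 4, 8)
  A <- A / rowSums(A) * runif(4, 0.5, 1)   # sub-unit masses (registry drain)
  Aobj <- structure(list(A = A, S = S, H = H, W = W, Hq = H, Wq = W),
                    class = "coarse_attention")
  up <- upsampler_params(d)
  up$ffn_w2$val <- matrix(rnorm(d), 1, d)  # make refinement genuinely active
  up$ffn_b2$val <- 0.3
  qf <- matrix(rnorm(16 * d), 16, d); sf <- matrix(rnorm(32 * d), 32, d)
  res <- upsample_attention(Aobj, up, qf, sf, K = 5L)
  expect_equal(rowSums(res$A), res$mass, tolerance = 1e-5)
  expect_true(all(res$A >= -1e-12))
})

test_that("the refinement factor is strictly positive for finite inputs", {
  y <- c(-30, -10, -1, 0, 1, 10, 30)
  factor <- 1 + ifelse(y > 0, y, exp(pmin(y, 0)) - 1)
  expect_true(all(factor > 0))
  # and the package's ELU agrees
  expect_equal(ns$ag_val(ns$ag_elu(ns$ag_const(y))), ifelse(y > 0, y, exp(pmin(y, 0)) - 1))
})

test_that("the top-K chain quadruples across decoder stages (8 -> 32 -> 128)", {
  # the 32/128 refined-location consequence holds at the native 256-px
  # geometry, where the coarse grid is 8x8
  set.seed(40)
  model <- icseg_model("tiny", seed = 2)
  ep <- random_episode(256L, 1L)
  att <- predict_episode(model, ep, K_base = 8L,
                         export_attention = TRUE)$stage_attention
  expect_equal(dim(att$stride32$A), c(64L, 64L))     # 8x8 coarse grid
  expect_equal(att$stride16$K, 32L)
  expect_equal(att$stride8$K, 128L)
})

test_that("excessive K is clamped with a warning", {
  S <- 1L; H <- 2L; W <- 2L
  A <- matrix(1 / 4, 4, 4)
  Aobj <- structure(list(A = A, S = S, H = H, W = W, Hq = H, Wq = W),
                    class = "coarse_attention")
  up <- upsampler_params(2L)
  expect_warning(
    res <- upsample_attention(Aobj, up, matrix(0, 16, 2), matrix(0, 16, 2), K = 99L),
    "clamped")
  expect_equal(res$K, 16L)
})
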