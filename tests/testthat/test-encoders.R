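test_that("configuration invariants are enforced", {
  expect_error(encoder_config(stage_widths = c(8, 16), stage_depths = c(1, 1)),
               "4 stages")
  expect_error(encoder_config(stage_widths = c(8, 16, 24, -1),
                              stage_depths = c(1, 1, 1, 1)), "positive")
  expect_error(encoder_config(in_channels = 3L), "in_channels")
})

test_that("receptive fields match the reference ratios, analytically and empirically", {
  for (preset in c("tiny", "paper")) {
    enc <- build_encoder(encoder_config(preset = preset))
    rf <- theoretical_receptive_field(enc, 256L)
    expect_equal(rf$rf_px, c(7, 19, 43, 91, 187))
    expect_equal(round(100 * rf$fraction, 1), c(2.7, 7.4, 16.8, 35.5, 73.0),
                 tolerance = 0.0501)
  }
  enc <- build_encoder(encoder_config(preset = "tiny"))
  for (i in seq_len(5)) {
    stage <- c("stem", paste0("stage", 1:4))[i]
    expect_identical(as.integer(empirical_receptive_field(enc, stage)),
                     c(7L, 19L, 43L, 91L, 187L)[i])
  }
})

test_that("a lone 1x1 convolution has a receptive field of 1 pixel", {
  r <- 1; j <- 1
  r <- r + (1 - 1) * j
  enc <- build_encoder(encoder_config(preset = "tiny"))
  one_by_one <- Filter(function(l) l$k == 1L, enc$layers)
  expect_gt(length(one_by_one), 0)
  expect_equal(r, 1)  # pointwise layers never widen the accumulated RF
  rf_with <- theoretical_receptive_field(enc)$rf_px
  # dropping all 1x1 layers leaves the accumulation unchanged
  enc2 <- enc; enc2$layers <- Filter(function(l) l$k > 1L, enc$layers)
  expect_equal(theoretical_receptive_field(enc2)$rf_px, rf_with)
})

test_that("query pyramid has the advertised geometry and z-scored levels", {
  set.seed(21)
  enc <- build_encoder(encoder_config(preset = "tiny"))
  img <- matrix(runif(256 * 256), 256, 256)
  fp <- encode_query(enc, img)
  expect_equal(as.integer(vapply(fp$levels, function(x) dim(x)[1], numeric(1))),
               c(128L, 64L, 32L, 16L, 8L))
  for (lv in fp$levels) {
    v <- as.vector(lv)
    expect_lt(abs(mean(v)), 1e-4)
    expect_lt(abs(mean(v^2) - 1), 1e-4)
  }
  # determinism and sanity
  fp2 <- encode_query(enc, img)
  expect_identical(fp$levels, fp2$levels)
  fp0 <- encode_query(enc, matrix(0, 256, 256))
  expect_true(all(vapply(fp0$levels, function(x) all(is.finite(x)), logical(1))))
  # no accidental mirror symmetry
  fpf <- encode_query(enc, img[, 256:1])
  expect_gt(max(abs(fp$levels[["32"]] - fpf$levels[["32"]])), 1e-6)
})

test_that("support encoding is per-example and uses the mask channel", {
  set.seed(22)
  enc2 <- build_encoder(encoder_config(in_channels = 2L, preset = "tiny"))
  imgs <- replicate(3, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  msks <- replicate(3, matrix(rbinom(64 * 64, 1, 0.3), 64, 64), simplify = FALSE)
  fp <- encode_support(enc2, imgs, msks)
  expect_equal(dim(fp$levels[["32"]]), c(2L, 2L, 32L, 3L))
  # permutation of the support axis permutes features identically
  perm <- c(3L, 1L, 2L)
  fpp <- encode_support(enc2, imgs[perm], msks[perm])
  expect_equal(fpp$levels[["32"]], fp$levels[["32"]][, , , perm, drop = FALSE])
  # all-zero vs all-one mask must change the features
  m0 <- list(matrix(0, 64, 64)); m1 <- list(matrix(1, 64, 64))
  f0 <- encode_support(enc2, imgs[1], m0)
  f1 <- encode_support(enc2, imgs[1], m1)
  expect_gt(max(abs(f0$levels[["32"]] - f1$levels[["32"]])), 1e-6)
  # contract errors
  expect_error(encode_support(enc2, imgs, msks[1:2]), "episode error")
  expect_error(encode_support(enc2, imgs[1], list(matrix(0.5, 64, 64))), "binary")
})

test_that("EMA updates are exact and compose multiplicatively", {
  enc <- build_encoder(encoder_config(preset = "tiny"))
  st <- ema_init(enc, decay = 0.9)
  # scalar check: shadow 1, online 3, decay 0.9 -> 1.2
  st2 <- st; st2$shadow <- list(a = 1);
  expect_equal(ema_update(structure(list(decay = 0.9, shadow = list(a = 1)),
                                    class = "ema_state"),
                          list(a = 3))$shadow$a, 1.2)
  # decay 1 fixed point / decay 0 full copy
  online <- lapply(enc$params, ns$ag_val)
  frozen <- lapply(online, function(x) x + 1)
  s1 <- structure(list(decay = 1, shadow = frozen), class = "ema_state")
  expect_equal(ema_update(s1, enc$params)$shadow, frozen)
  s0 <- structure(list(decay = 0, shadow = frozen), class = "ema_state")
  expect_equal(ema_update(s0, enc$params)$shadow, online)
  # two updates with decay b equal one with b^2 when online is frozen
  b <- 0.8
  sa <- structure(list(decay = b, shadow = frozen), class = "ema_state")
  sa <- ema_update(ema_update(sa, enc$params), enc$params)
  sb <- structure(list(decay = b^2, shadow = frozen), class = "ema_state")
  sb <- ema_update(sb, enc$params)
  expect_equal(sa$shadow, sb$shadow, tolerance = 1e-12)
  # shape mismatch is refused
  bad <- online; bad[[1]] <- matrix(0, 2, 2)
  expect_error(ema_update(structure(list(decay = 0.5, shadow = bad),
                                    class = "ema_state"), enc$params),
               "shape mismatch")
})
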