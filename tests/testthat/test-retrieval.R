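make_pool <- function(n, geometry = 64L, task = NULL) {
  task <- task %||% { set.seed(81); generate_task(geometry = geometry) }
  lapply(seq_len(n), function(i) {
    ep <- generate_episode(task, 1L)
    list(image = ep$query_image, mask = ep$query_mask)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the index has one entry per coarse cell and is deterministic", {
  set.seed(82)
  model <- icseg_model("tiny", seed = 12)
  pool <- make_pool(3)
  idx1 <- build_index(pool, model)
  expect_equal(nrow(idx1$embeddings), 3 * 2 * 2)   # 64/32 = 2x2 grid
  expect_equal(idx1$grid, c(H = 2L, W = 2L))
  idx2 <- build_index(pool, model)
  expect_identical(idx1$embeddings, idx2$embeddings)
  expect_error(build_index(list(), model), "empty pool")
})

test_that("index entries equal hand-computed key projections of EMA features", {
  set.seed(83)
  model <- icseg_model("tiny", seed = 13)
  pool <- make_pool(2)
  idx <- build_index(pool, model)
  img <- pool[[2]]$image
  x <- ns$ag_const(array(img, c(64, 64, 1, 1)))
  f32 <- ns$ag_val(ns$encoder_forward(model$enc_map, x,
                                      override = model$ema$shadow)$levels[["32"]])
  # entry for image 2, cell (h=1, w=2) under row-major flattening
  want <- as.numeric(f32[1, 2, , 1] %*% ns$ag_val(model$attn$W_K))
  got <- idx$embeddings[idx$image_id == 2 & idx$cell == 2, ]
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
})

test_that("contour sampling stays on the boundary and handles degeneracies", {
  m <- matrix(0, 32, 32); m[10:20, 10:20] <- 1
  set.seed(84)
  pts <- sample_contour_locations(m, 12L)
  edge <- mask_edge_band(m, 1L)
  for (i in seq_len(nrow(pts))) expect_equal(edge[pts[i, 1], pts[i, 2]], 1)
  # n exceeding the boundary length repeats but stays on the boundary
  small <- matrix(0, 16, 16); small[8:9, 8:9] <- 1
  pts2 <- sample_contour_locations(small, 50L)
  expect_equal(nrow(pts2), 50L)
  edge2 <- mask_edge_band(small, 1L)
  expect_true(all(edge2[pts2] == 1))
  expect_warning(p0 <- sample_contour_locations(matrix(0, 16, 16), 4L), "empty")
  expect_equal(nrow(p0), 4L)
  set.seed(85); a <- sample_contour_locations(m, 6L)
  set.seed(85); b <- sample_contour_locations(m, 6L)
  expect_identical(a, b)
})

test_that("an exact duplicate of the query ranks first; S = N exhausts the pool", {
  set.seed(86)
  model <- icseg_model("tiny", seed = 14)
  # align the two projections so the bilinear similarity is a positive
  # semi-definite form; identical embeddings are then self-maximal
  model$attn$W_K$val <- model$attn$W_Q$val <- diag(nrow(model$attn$W_Q$val))
  pool <- make_pool(5)
  idx <- build_index(pool, model)
  q <- pool[[4]]
  set.seed(87)
  cs <- build_custom_support(q$image, q$mask, idx, S = 1L, model, pool)
  expect_equal(cs$image_ids, 4L)
  cs_all <- build_custom_support(q$image, q$mask, idx, S = 5L, model, pool)
  expect_setequal(cs_all$image_ids, 1:5)
})

test_that("degenerate retrieval (custom = generic) gives exactly zero increment", {
  set.seed(88)
  model <- icseg_model("tiny", seed = 15)
  task <- generate_task(geometry = 64L)
  sampler <- function(N, M) {
    list(pool = make_pool(N, task = task),
         queries = make_pool(M, task = task))
  }
  res <- delta_dice_experiment(sampler, model,
                               retrieval_config(N = 6L, M = 3L, S = 2L,
                                                repetitions = 2L),
                               degenerate = TRUE)
  expect_identical(res$mean_delta, 0)
  expect_true(all(res$per_query$delta == 0))
})

test_that("retrieval picks within-cluster supports above chance", {
  fx <- fixture_trained_model()
  set.seed(89)
  taskA <- generate_task(geometry = 64L); taskA$fg <- 0.8; taskA$bg <- 0.25
  taskA$shape_family <- "disk"; taskA$distractors <- 0L
  taskB <- generate_task(geometry = 64L); taskB$fg <- 0.2; taskB$bg <- 0.75
  taskB$shape_family <- "rectangle"; taskB$distractors <- 0L
  draw <- function(task) {
    ep <- generate_episode(task, 1L)
    list(image = ep$query_image, mask = ep$query_mask)
  }
  pool <- c(lapply(1:15, function(i) draw(taskA)),
            lapply(1:15, function(i) draw(taskB)))
  cluster <- rep(c("A", "B"), each = 15)
  idx <- build_index(pool, fx$model)
  S <- 4L
  picks <- lapply(1:50, function(i) {
    qtask <- if (i %% 2 == 0) taskA else taskB
    q <- draw(qtask)
    cs <- build_custom_support(q$image, q$mask, idx, S, fx$model, pool)
    cluster[cs$image_ids] == (if (i %% 2 == 0) "A" else "B")
  })
  hits <- sum(unlist(picks)); total <- length(unlist(picks))
  # above chance at alpha = 0.01 over 50 queries
  expect_lt(stats::binom.test(hits, total, 0.5, alternative = "greater")$p.value,
            0.01)
  # regression bound at the level this seed-pinned fixture attains (~0.72)
  expect_gte(hits / total, 0.65)
})
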