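# ---------------------------------------------------------------------------
# Synthetic in-context episodes.
#
# A task is a family of scenes sharing one segmentation semantic: a shape
# class (disk, rectangle, ring, blob-union, thin-vessel) drawn with a
# task-specific appearance (foreground/background intensity, noise level),
# optional same-intensity distractor shapes from other families, and a
# spatial offset between the query target and the support targets so that
# the global cross-attention is actually exercised. Held-out tasks are
# disjoint from training tasks.
# ---------------------------------------------------------------------------

SHAPE_FAMILIES <- c("disk", "rectangle", "ring", "blob-union", "thin-vessel")

#' Sample a synthetic task specification
#'
#' @param task_id identifier; generated when `NULL`.
#' @param held_out reserve this task for testing (never in training streams).
#' @param geometry raster side length in pixels.
#' @return a `task_spec` list.
#' @export
generate_task <- function(task_id = NULL, held_out = FALSE, geometry = 256L) {
  fam <- sample(SHAPE_FAMILIES, 1L)
  dark_fg <- stats::runif(1) < 0.5
  bg <- stats::runif(1, 0.15, 0.40)
  fg <- stats::runif(1, 0.60, 0.85)
  if (dark_fg) { tmp <- bg; bg <- fg; fg <- tmp }
  structure(list(
    task_id = task_id %||% sprintf("task-%s-%05d", fam, sample.int(99999L, 1L)),
    shape_family = fam,
    fg = fg, bg = bg,
    noise_sd = stats::runif(1, 0.02, 0.06),
    offset_range = stats::runif(1, 0.05, 0.25),      # fraction of width
    size_range = sort(stats::runif(2, 0.10, 0.22)),  # radius fraction of width
    distractors = sample(0:2, 1L),
    held_out = isTRUE(held_out),
    geometry = as.integer(geometry)
  ), class = "task_spec")
}

# --- shape rasterizers (binary masks on an n x n grid) ----------------------

.grid_xy <- function(n) {
  list(x = matrix(rep(seq_len(n), each = n), n, n),
       y = matrix(rep(seq_len(n), times = n), n, n))
}

.draw_shape <- function(family, n, cx, cy, r) {
  g <- .grid_xy(n)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  m <- switch(family,
    disk = d2 <= r^2,
    rectangle = abs(g$x - cx) <= r & abs(g$y - cy) <= 0.7 * r,
    ring = d2 <= r^2 & d2 >= (0.55 * r)^2,
    "blob-union" = {
      m <- matrix(FALSE, n, n)
      for (k in 1:3) {
        dx <- stats::runif(1, -0.5, 0.5) * r; dy <- stats::runif(1, -0.5, 0.5) * r
        m <- m | ((g$x - cx - dx)^2 + (g$y - cy - dy)^2 <= (0.6 * r)^2)
      }
      m
    },
    "thin-vessel" = {
      m <- matrix(FALSE, n, n)
      len <- max(8L, round(2.5 * r))
      th <- stats::runif(1, 0, 2 * pi)
      px <- cx; py <- cy
      half <- max(1, round(n / 90))
      for (k in seq_len(len)) {
        th <- th + stats::rnorm(1, 0, 0.25)
        px <- px + cos(th); py <- py + sin(th)
        xi <- round(px); yi <- round(py)
        if (xi < 2 || xi > n - 1 || yi < 2 || yi > n - 1) break
        m[max(1, xi - half):min(n, xi + half), max(1, yi - half):min(n, yi + half)] <- TRUE
      }
      m
    },
    stop("unknown shape family: ", family))
  m * 1
}

.render_scene <- function(task, center) {
  n <- task$geometry
  r <- stats::runif(1, task$size_range[1], task$size_range[2]) * n
  mask <- .draw_shape(task$shape_family, n, center[1], center[2], r)
  tries <- 0L
  while (sum(mask) < 10 && tries < 20L) {   # enforce the minimum-area rule
    r <- r * 1.3
    mask <- .draw_shape(task$shape_family, n, center[1], center[2], r)
    tries <- tries + 1L
  }
  img <- matrix(task$bg, n, n)
  img[mask > 0] <- task$fg
  if (task$distractors > 0L) {
    others <- setdiff(SHAPE_FAMILIES, task$shape_family)
    for (k in seq_len(task$distractors)) {
      dfam <- sample(others, 1L)
      dc <- stats::runif(2, 0.15, 0.85) * n
      dr <- stats::runif(1, task$size_range[1], task$size_range[2]) * n
      dm <- .draw_shape(dfam, n, dc[1], dc[2], dr)
      img[dm > 0 & mask == 0] <- task$fg      # same intensity as the target
    }
  }
  img <- img + matrix(stats::rnorm(n * n, sd = task$noise_sd), n, n)
  img <- as.matrix(EBImage::gblur(img, sigma = 0.6))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate one synthetic episode
#'
#' The query target is translated by up to `offset_range` relative to the
#' support targets; all scenes share the task's appearance model and every
#' mask covers at least 10 pixels.
#'
#' @param task a `task_spec`.
#' @param S support set size (>= 1).
#' @return an episode list (`query_image`, `query_mask`, `support_images`,
#'   `support_masks`, `task_id`).
#' @export
generate_episode <- function(task, S) {
  stopifnot(S >= 1)
  n <- task$geometry
  base <- stats::runif(2, 0.3, 0.7) * n
  sup_images <- vector("list", S); sup_masks <- vector("list", S)
  for (s in seq_len(S)) {
    jit <- stats::rnorm(2, 0, 0.03 * n)
    sc <- .render_scene(task, pmin(pmax(base + jit, 0.15 * n), 0.85 * n))
    sup_images[[s]] <- sc$image; sup_masks[[s]] <- sc$mask
  }
  off <- stats::runif(2, -1, 1) * task$offset_range * n
  qc <- pmin(pmax(base + off, 0.15 * n), 0.85 * n)
  qs <- .render_scene(task, qc)
  list(query_image = qs$image, query_mask = qs$mask,
       support_images = sup_images, support_masks = sup_masks,
       task_id = task$task_id)
}

#' DICE overlap score
#'
#' `2 |P intersect T| / (|P| + |T|)` on binary rasters. Both-empty is
#' defined as 1 (agreement that nothing is present); empty-vs-nonempty is 0.
#'
#' @param pred_mask,target binary rasters of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, target) {
  if (!identical(dim(pred_mask), dim(target)))
    stop("pred and target shapes differ")
  sp <- sum(pred_mask); st <- sum(target)
  if (sp + st == 0) return(1)
  2 * sum(pred_mask * target) / (sp + st)
}

#' Evaluate a model over tasks and support sizes
#'
#' For each query a fresh support set is resampled (never reused between
#' queries). Scores are averaged first over queries within a task, then over
#' tasks; a shape-family aggregate is also returned.
#'
#' @param model an `icseg_model`, or a function `(episode) -> mask` for
#'   oracle/baseline probes.
#' @param tasks list of `task_spec`s.
#' @param S_values support sizes to evaluate.
#' @param episodes_per_task queries per (task, S) cell.
#' @param K_base inference base top-K.
#' @param threshold binarization threshold for predicted probabilities.
#' @return list with `per_task` (data.frame task_id, family, S, mean_dice),
#'   `per_S` (task-averaged), `per_family_S`.
#' @export
evaluate_model <- function(model, tasks, S_values = c(2, 4, 8, 16),
                           episodes_per_task = 5L, K_base = 8L,
                           threshold = 0.5) {
  predictor <- if (is.function(model)) model else
    function(ep) predict_episode(model, ep, K_base = K_base)$mask
  rows <- list()
  for (task in tasks) {
    for (S in S_values) {
      scores <- vapply(seq_len(episodes_per_task), function(i) {
        ep <- generate_episode(task, S)
        pm <- (predictor(ep) >= threshold) * 1
        dice_score(pm, ep$query_mask)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        task_id = task$task_id, family = task$shape_family, S = S,
        mean_dice = mean(scores))
    }
  }
  per_task <- do.call(rbind, rows)
  per_S <- stats::aggregate(mean_dice ~ S, per_task, mean)
  per_family_S <- stats::aggregate(mean_dice ~ family + S, per_task, mean)
  list(per_task = per_task, per_S = per_S, per_family_S = per_family_S)
}

#' Episode stream over a set of tasks
#'
#' Uniform task resampling (each step draws a task uniformly, then an
#' episode), mirroring dataset/task-balanced training. Each task is backed
#' by a finite pool of rendered scenes — as with a finite set of annotated
#' slices — from which the query and a fresh support combination are drawn
#' without replacement.
#'
#' @param tasks list of `task_spec`s (held-out tasks are refused).
#' @param S support size.
#' @param scenes_per_task size of each task's scene pool (built lazily).
#' @return function of the step index returning an episode.
#' @export
make_episode_stream <- function(tasks, S, scenes_per_task = 40L) {
  if (any(vapply(tasks, function(t) t$held_out, logical(1))))
    stop("held-out tasks must not enter a training stream")
  pools <- vector("list", length(tasks))
  function(step) {
    ti <- sample.int(length(tasks), 1L)
    if (is.null(pools[[ti]]))
      pools[[ti]] <<- generate_scene_pool(tasks[[ti]], scenes_per_task)
    pool_episode(pools[[ti]], S, task_id = tasks[[ti]]$task_id)
  }
}

#' Render a finite scene pool for a task
#'
#' @param task a `task_spec`.
#' @param n number of scenes.
#' @return list of `list(image, mask)` records sharing the task's base
#'   placement (so support/query offsets stay within `offset_range`).
#' @export
generate_scene_pool <- function(task, n = 40L) {
  g <- task$geometry
  base <- stats::runif(2, 0.3, 0.7) * g
  lapply(seq_len(n), function(i) {
    off <- stats::runif(2, -1, 1) * task$offset_range * g
    ctr <- pmin(pmax(base + off, 0.15 * g), 0.85 * g)
    .render_scene(task, ctr)
  })
}

#' Assemble an episode from a scene pool
#'
#' Draws a query and S distinct support scenes without replacement.
#'
#' @param pool a [generate_scene_pool()] result.
#' @param S support size (`S + 1 <= length(pool)`).
#' @param task_id carried into the episode.
#' @return an episode list.
#' @export
pool_episode <- function(pool, S, task_id = "pool") {
  stopifnot(S + 1L <= length(pool))
  sel <- sample.int(length(pool), S + 1L)
  q <- pool[[sel[1]]]
  list(query_image = q$image, query_mask = q$mask,
       support_images = lapply(pool[sel[-1]], `[[`, "image"),
       support_masks = lapply(pool[sel[-1]], `[[`, "mask"),
       task_id = task_id)
}

#' Scene with two candidate segmentation semantics
#'
#' Generates an episode whose scenes each contain both a disk and a
#' rectangle at the same foreground intensity; the returned episode's
#' targets follow `target` ("disk" or "rectangle"), and the query's masks
#' for both classes are attached for support-swap experiments.
#'
#' @param target which class the support masks annotate.
#' @param S support size.
#' @param geometry raster side length.
#' @param appearance optional list(fg, bg, noise_sd).
#' @return an episode with extra fields `query_mask_disk`,
#'   `query_mask_rectangle`.
#' @export
generate_two_class_episode <- function(target = c("disk", "rectangle"), S,
                                       geometry = 64L, appearance = NULL) {
  target <- match.arg(target)
  n <- as.integer(geometry)
  ap <- appearance %||% list(fg = 0.75, bg = 0.25, noise_sd = 0.03)
  draw_scene <- function() {
    img <- matrix(ap$bg, n, n)
    placed <- FALSE
    while (!placed) {
      c1 <- stats::runif(2, 0.2, 0.8) * n
      c2 <- stats::runif(2, 0.2, 0.8) * n
      if (sqrt(sum((c1 - c2)^2)) > 0.35 * n) placed <- TRUE
    }
    r <- stats::runif(1, 0.10, 0.16) * n
    md <- .draw_shape("disk", n, c1[1], c1[2], r)
    mr <- .draw_shape("rectangle", n, c2[1], c2[2], r)
    img[md > 0] <- ap$fg
    img[mr > 0] <- ap$fg
    img <- img + matrix(stats::rnorm(n * n, sd = ap$noise_sd), n, n)
    img <- pmin(pmax(as.matrix(EBImage::gblur(img, sigma = 0.6)), 0), 1)
    list(image = img, disk = md, rectangle = mr)
  }
  sup_images <- vector("list", S); sup_masks <- vector("list", S)
  for (s in seq_len(S)) {
    sc <- draw_scene()
    sup_images[[s]] <- sc$image
    sup_masks[[s]] <- sc[[target]]
  }
  qs <- draw_scene()
  list(query_image = qs$image, query_mask = qs[[target]],
       query_mask_disk = qs$disk, query_mask_rectangle = qs$rectangle,
       support_images = sup_images, support_masks = sup_masks,
       task_id = paste0("two-class-", target))
}
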