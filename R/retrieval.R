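# ---------------------------------------------------------------------------
# Content-based support retrieval.
#
# The cross-attention mapper doubles as a retrieval system: every annotated
# pool image is embedded with the EMA attention-mapper encoder at the
# coarsest level and projected with the attention key projection W_K. A
# query's local embeddings (projected with W_Q) at locations sampled around
# its predicted mask contour are matched against the index with the same
# bilinear similarity used inside the attention softmax, and the most
# frequently matched pool images form a query-personalized support set.
# ---------------------------------------------------------------------------

#' Build an embedding index over an annotated pool
#'
#' @param pool list of records, each `list(image =, mask =)` (query-sized
#'   matrices).
#' @param model a trained `icseg_model` (the EMA encoder and W_K are used).
#' @return an `embedding_index`: `embeddings` (|pool|*H*W x d, key-projected),
#'   `image_id` / `cell` per entry, grid geometry.
#' @export
build_index <- function(pool, model) {
  if (length(pool) == 0L) stop("empty pool")
  embs <- vector("list", length(pool))
  WK <- ag_val(model$attn$W_K)
  for (i in seq_along(pool)) {
    img <- pool[[i]]$image
    x <- ag_const(array(img, c(nrow(img), ncol(img), 1L, 1L)))
    fp <- encoder_forward(model$enc_map, x, override = model$ema$shadow)
    f32 <- ag_val(fp$levels[["32"]])
    embs[[i]] <- flatten_hw(f32) %*% WK
  }
  gH <- nrow(pool[[1]]$image) %/% 32L
  gW <- ncol(pool[[1]]$image) %/% 32L
  ncell <- gH * gW
  structure(list(
    embeddings = do.call(rbind, embs),
    image_id = rep(seq_along(pool), each = ncell),
    cell = rep(seq_len(ncell), times = length(pool)),
    grid = c(H = gH, W = gW),
    d = ncol(embs[[1]])
  ), class = "embedding_index")
}

#' Sample locations around a mask contour
#'
#' @param mask binary matrix (typically a predicted mask).
#' @param n number of points (drawn uniformly from the boundary pixels,
#'   with replacement if the boundary is shorter than `n`).
#' @return n x 2 matrix of (row, col) coordinates. An empty mask falls back
#'   to the image centre with a warning.
#' @export
sample_contour_locations <- function(mask, n = 8L) {
  if (sum(mask) == 0) {
    warning("empty mask: falling back to the image centre")
    ctr <- matrix(c(nrow(mask) %/% 2L, ncol(mask) %/% 2L), 1L, 2L)
    return(ctr[rep(1L, n), , drop = FALSE])
  }
  boundary <- which(mask_edge_band(mask, 1L) > 0, arr.ind = TRUE)
  sel <- sample.int(nrow(boundary), n, replace = nrow(boundary) < n)
  boundary[sel, , drop = FALSE]
}

# map pixel coordinates to flattened coarse-cell indices (row-major)
.pix_to_cell <- function(coords, img_h, img_w, gH, gW) {
  ch <- pmin(pmax(ceiling(coords[, 1] / (img_h / gH)), 1L), gH)
  cw <- pmin(pmax(ceiling(coords[, 2] / (img_w / gW)), 1L), gW)
  (ch - 1L) * gW + cw
}

#' Build a query-personalized support set by retrieval
#'
#' @param query_image query raster.
#' @param draft_mask mask whose contour drives the retrieval (typically the
#'   prediction under a generic support set).
#' @param index an [build_index()] result from the same checkpoint.
#' @param S support set size.
#' @param model the model (for query-side embeddings, W_Q projection).
#' @param pool the annotated pool the index was built from.
#' @param contour_samples number of contour locations to match.
#' @return list with `support_images`, `support_masks`, `image_ids`.
#' @export
build_custom_support <- function(query_image, draft_mask, index, S, model,
                                 pool, contour_samples = 8L) {
  x <- ag_const(array(query_image, c(nrow(query_image), ncol(query_image), 1L, 1L)))
  fp <- encoder_forward(model$enc_map, x)
  q32 <- flatten_hw(ag_val(fp$levels[["32"]])) %*% ag_val(model$attn$W_Q)
  pts <- sample_contour_locations(draft_mask, contour_samples)
  cells <- .pix_to_cell(pts, nrow(query_image), ncol(query_image),
                        index$grid["H"], index$grid["W"])
  # normalized cross-correlation between query- and key-projected embeddings
  # (cosine; immune to per-entry norm "hubs")
  En <- index$embeddings / sqrt(rowSums(index$embeddings^2) + 1e-12)
  Qn <- q32 / sqrt(rowSums(q32^2) + 1e-12)
  sims <- Qn[cells, , drop = FALSE] %*% t(En)                 # (n_pts, entries)
  best_entry <- apply(sims, 1, which.max)
  best_img <- index$image_id[best_entry]
  best_sim <- sims[cbind(seq_along(best_entry), best_entry)]
  # rank pool images by match frequency, then by best similarity
  tab <- data.frame(img = best_img, sim = best_sim)
  agg <- stats::aggregate(sim ~ img, tab, max)
  agg$freq <- as.vector(table(factor(tab$img, levels = agg$img)))
  agg <- agg[order(-agg$freq, -agg$sim, agg$img), ]
  chosen <- agg$img
  if (length(chosen) < S) {
    # pad with the next most similar pool images overall
    col_best <- apply(sims, 2, max)
    img_best <- tapply(col_best, index$image_id, max)
    rest <- as.integer(names(sort(img_best, decreasing = TRUE)))
    chosen <- c(chosen, setdiff(rest, chosen))
  }
  chosen <- utils::head(chosen, S)
  list(support_images = lapply(pool[chosen], `[[`, "image"),
       support_masks = lapply(pool[chosen], `[[`, "mask"),
       image_ids = chosen)
}

#' Retrieval experiment configuration
#'
#' @param N labeled pool size.
#' @param M unlabeled query count.
#' @param S support set size.
#' @param repetitions Monte-Carlo repetitions (pools resampled each time).
#' @param contour_samples contour locations per query.
#' @return a `retrieval_config` list.
#' @export
retrieval_config <- function(N = 150L, M = 100L, S = 8L, repetitions = 10L,
                             contour_samples = 8L) {
  stopifnot(N >= S, repetitions >= 1)
  structure(list(N = as.integer(N), M = as.integer(M), S = as.integer(S),
                 repetitions = as.integer(repetitions),
                 contour_samples = as.integer(contour_samples)),
            class = "retrieval_config")
}

#' Monte-Carlo generic-vs-custom support experiment
#'
#' For each repetition: a labeled pool and query set are sampled via
#' `sampler`; one fixed generic support set of size S is drawn from the
#' pool; each query is predicted with it, contour locations of the
#' prediction drive retrieval of a custom support set, the query is
#' re-predicted, and the DICE increment is recorded.
#'
#' @param sampler function `(N, M)` returning
#'   `list(pool = list(list(image, mask)), queries = list(list(image, mask)))`.
#' @param model a trained `icseg_model`.
#' @param cfg a [retrieval_config()].
#' @param K_base inference base top-K.
#' @param degenerate if TRUE the custom support is forced equal to the
#'   generic one (control arm; the increment is identically 0).
#' @return list with `mean_delta`, `per_repetition` data.frame, and
#'   `per_query` records.
#' @export
delta_dice_experiment <- function(sampler, model, cfg = retrieval_config(),
                                  K_base = 8L, degenerate = FALSE) {
  reps <- vector("list", cfg$repetitions)
  per_query <- list()
  for (r in seq_len(cfg$repetitions)) {
    dat <- sampler(cfg$N, cfg$M)
    index <- if (!degenerate) build_index(dat$pool, model) else NULL
    gen_ids <- sample.int(length(dat$pool), cfg$S)
    gen_sup <- list(images = lapply(dat$pool[gen_ids], `[[`, "image"),
                    masks = lapply(dat$pool[gen_ids], `[[`, "mask"))
    deltas <- numeric(length(dat$queries))
    for (qi in seq_along(dat$queries)) {
      q <- dat$queries[[qi]]
      ep_gen <- list(query_image = q$image, query_mask = q$mask,
                     support_images = gen_sup$images,
                     support_masks = gen_sup$masks)
      pm_gen <- predict_episode(model, ep_gen, K_base = K_base)$mask
      d_gen <- dice_score((pm_gen >= 0.5) * 1, q$mask)
      if (degenerate) {
        custom <- gen_sup
      } else {
        cs <- build_custom_support(q$image, (pm_gen >= 0.5) * 1, index,
                                   cfg$S, model, dat$pool,
                                   cfg$contour_samples)
        custom <- list(images = cs$support_images, masks = cs$support_masks)
      }
      ep_cus <- list(query_image = q$image, query_mask = q$mask,
                     support_images = custom$images,
                     support_masks = custom$masks)
      pm_cus <- predict_episode(model, ep_cus, K_base = K_base)$mask
      d_cus <- dice_score((pm_cus >= 0.5) * 1, q$mask)
      deltas[qi] <- d_cus - d_gen
      per_query[[length(per_query) + 1L]] <-
        data.frame(repetition = r, query = qi, dice_generic = d_gen,
                   dice_custom = d_cus, delta = deltas[qi])
    }
    reps[[r]] <- data.frame(repetition = r, mean_delta = mean(deltas))
  }
  per_rep <- do.call(rbind, reps)
  list(mean_delta = mean(per_rep$mean_delta), per_repetition = per_rep,
       per_query = do.call(rbind, per_query))
}
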