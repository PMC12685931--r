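# ---------------------------------------------------------------------------
# Episodic training: AdamW with decoupled weight decay, step-wise learning
# rate halving, a scheduled attention-upsampler top-K, per-step EMA teacher
# updates and early stopping on the validation loss.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol (155k steps, base learning rate
#' 1e-4 halved at 75k and 100k steps, weight decay 1e-3, support size 16,
#' upsampler base top-K 5 for the first 125k steps then 24, validation every
#' 5k steps). Desk-scale runs override `steps`, schedules and
#' `support_size`.
#'
#' @param steps number of optimizer steps.
#' @param base_lr base learning rate.
#' @param lr_halving_steps steps at which the learning rate is halved.
#' @param weight_decay decoupled weight decay coefficient.
#' @param support_size episodes' support set size S.
#' @param topk_schedule data.frame with columns `until` (inclusive step
#'   bound, last row `Inf`) and `K` (base top-K).
#' @param val_every validation period in steps.
#' @param early_stop_patience validation rounds without improvement before
#'   stopping.
#' @param augmentations probabilities from [augment_config()].
#' @param loss a [loss_config()].
#' @param seed RNG seed for the run.
#' @return a `train_config` list.
#' @export
train_config <- function(steps = 155000L, base_lr = 1e-4,
                         lr_halving_steps = c(75000L, 100000L),
                         weight_decay = 1e-3, support_size = 16L,
                         topk_schedule = data.frame(until = c(125000, Inf),
                                                    K = c(5, 24)),
                         val_every = 5000L, early_stop_patience = 5L,
                         augmentations = augment_config(),
                         loss = loss_config(), seed = 0L) {
  if (is.unsorted(topk_schedule$until))
    stop("topk_schedule boundaries must be increasing")
  structure(list(steps = as.integer(steps), base_lr = base_lr,
                 lr_halving_steps = lr_halving_steps,
                 weight_decay = weight_decay,
                 support_size = as.integer(support_size),
                 topk_schedule = topk_schedule, val_every = as.integer(val_every),
                 early_stop_patience = as.integer(early_stop_patience),
                 augmentations = augmentations, loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' @param step training step.
#' @param base_lr base learning rate.
#' @param halving_steps steps at which the rate is halved.
#' @return the scheduled learning rate.
#' @export
lr_at_step <- function(step, base_lr, halving_steps) {
  base_lr * 0.5^sum(step >= halving_steps)
}

#' Base top-K at a given step
#'
#' @param step training step.
#' @param schedule `topk_schedule` data.frame (`until`, `K`).
#' @return the scheduled base top-K.
#' @export
topk_at_step <- function(step, schedule) {
  schedule$K[which(step <= schedule$until)[1]]
}

# ------------------------------ AdamW optimizer -----------------------------

adamw_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) array(0, dim(p$val) %||% length(p$val))),
       v = lapply(params, function(p) array(0, dim(p$val) %||% length(p$val))),
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

adamw_step <- function(opt, params, lr, weight_decay) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    p$val <- p$val - lr * (upd + weight_decay * p$val)
  }
  opt
}

# ------------------------------- training loop ------------------------------

.eval_loss <- function(model, episodes, K_base, loss_cfg) {
  mean(vapply(episodes, function(ep) {
    pr <- model_forward(model, ep, K_base = K_base)$prob
    combined_loss(pr, ep$query_mask, loss_cfg)
  }, numeric(1)))
}

#' Train a model on an episode stream
#'
#' @param model an `icseg_model` (modified in place; also returned).
#' @param episode_stream function of the step index returning a fresh
#'   training episode.
#' @param cfg a [train_config()].
#' @param val_episodes list of fixed validation episodes (required for
#'   validation/early stopping; may be `NULL` to disable).
#' @param verbose print progress every validation round.
#' @return list with `model` (best-validation weights restored), `metrics`
#'   (data.frame: step, train_loss, val_loss, lr, K).
#' @export
train_model <- function(model, episode_stream, cfg = train_config(),
                        val_episodes = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  params <- collect_params(model)
  opt <- adamw_init(params)
  metrics <- vector("list", cfg$steps)
  best_val <- Inf
  best_snap <- NULL
  bad_rounds <- 0L
  stopped <- FALSE
  for (step in seq_len(cfg$steps)) {
    ep <- augment(episode_stream(step), cfg$augmentations)
    Kb <- topk_at_step(step, cfg$topk_schedule)
    fw <- model_forward(model, ep, K_base = Kb)
    loss <- .ag_loss(fw$logits, ep$query_mask, cfg$loss)
    lv <- as.numeric(ag_val(loss))
    if (!is.finite(lv))
      stop("training aborted: non-finite loss at step ", step)
    ag_backward(loss)
    lr <- lr_at_step(step, cfg$base_lr, cfg$lr_halving_steps)
    opt <- adamw_step(opt, params, lr, cfg$weight_decay)
    ag_zero_grad(params)
    model$ema <- ema_update(model$ema, model$enc_map$params)

    vl <- NA_real_
    if (!is.null(val_episodes) && step %% cfg$val_every == 0L) {
      vl <- .eval_loss(model, val_episodes, Kb, cfg$loss)
      if (vl < best_val - 1e-6) {
        best_val <- vl
        best_snap <- list(params = lapply(params, ag_val),
                          ema = model$ema$shadow)
        bad_rounds <- 0L
      } else {
        bad_rounds <- bad_rounds + 1L
      }
      if (verbose)
        message(sprintf("step %d  train %.4f  val %.4f  lr %.2e  K %d",
                        step, lv, vl, lr, Kb))
      if (bad_rounds >= cfg$early_stop_patience) stopped <- TRUE
    }
    metrics[[step]] <- data.frame(step = step, train_loss = lv, val_loss = vl,
                                  lr = lr, K = Kb)
    if (stopped) break
  }
  if (!is.null(best_snap)) {
    for (nm in names(params)) params[[nm]]$val <- best_snap$params[[nm]]
    model$ema$shadow <- best_snap$ema
  }
  list(model = model, metrics = do.call(rbind, metrics))
}
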