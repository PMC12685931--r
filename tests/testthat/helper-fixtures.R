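# Shared expensive fixtures, built once per test run.
#
# The trained tiny model is the study condition for the learning-behaviour
# and retrieval suites: tiny preset at 64x64 geometry, 96 training tasks
# backed by 24-scene pools, S = 4 episodes, 2000 AdamW steps (base lr 1e-3
# halved at 1500/1800, weight decay 1e-3, upsampler base top-K 5 then 8
# from step 1600 — the inference base; 24 would exceed the 64-px support
# grid), EMA decay 0.99, validation every 200 steps, patience 5.

.fixture_env <- new.env(parent = emptyenv())

fixture_tasks <- function() {
  if (is.null(.fixture_env$tasks)) {
    set.seed(7)
    .fixture_env$tasks <- list(
      train = lapply(1:96, function(i) generate_task(geometry = 64L)),
      test = lapply(1:6, function(i) generate_task(held_out = TRUE, geometry = 64L)))
  }
  .fixture_env$tasks
}

fixture_trained_model <- function() {
  if (is.null(.fixture_env$trained)) {
    tasks <- fixture_tasks()
    set.seed(7)
    model <- icseg_model("tiny", seed = 11, ema_decay = 0.99)
    val_eps <- lapply(1:8, function(i) generate_episode(tasks$train[[(i %% 96) + 1]], 4))
    cfg <- train_config(steps = 2000L, base_lr = 1e-3,
                        lr_halving_steps = c(1500L, 1800L),
                        weight_decay = 1e-3, support_size = 4L,
                        topk_schedule = data.frame(until = c(1600, Inf), K = c(5, 8)),
                        val_every = 200L, seed = 123L)
    res <- train_model(model, make_episode_stream(tasks$train, 4L, scenes_per_task = 24L),
                       cfg, val_episodes = val_eps)
    init_val <- {
      set.seed(123)
      m0 <- icseg_model("tiny", seed = 11, ema_decay = 0.99)
      ns$.eval_loss(m0, val_eps, 5L, loss_config())
    }
    .fixture_env$trained <- list(model = res$model, metrics = res$metrics,
                                 val_episodes = val_eps, init_val_loss = init_val)
  }
  .fixture_env$trained
}
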