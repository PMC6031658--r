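# Shared fixture builders. Everything is generated in code; pools used by
# several test files are cached per-session.

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_subjects = 4L, n_channels = 10L, sfreq = 200,
               epoch_window = c(-0.5, 1), n_epochs_per_condition = 16L,
               n_low_quality = 1L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

demo_cfg <- function(seed = 1L, ...) {
  args <- list(n_subjects = 8L, n_channels = 16L, sfreq = 250,
               n_epochs_per_condition = 24L, n_low_quality = 2L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

.pool_cache <- new.env(parent = emptyenv())
cached_pool <- function(key, maker) {
  if (!exists(key, envir = .pool_cache)) assign(key, maker(), envir = .pool_cache)
  get(key, envir = .pool_cache)
}

# hand-built epoch_set: deterministic sinusoid/noise content
toy_epochs <- function(n_ep = 4L, n_ch = 3L, n_s = 400L, sfreq = 200,
                       t0 = -0.5, fill = function(e, ch, t) stats::rnorm(length(t)),
                       labels = rep(c(1L, -1L), length.out = n_ep),
                       condition = "MI", modality = "MEG", seed = 99L) {
  t <- t0 + (seq_len(n_s) - 1L) / sfreq
  d <- array(0, dim = c(n_ep, n_ch, n_s))
  withr::with_seed(seed, {
    for (e in seq_len(n_ep)) for (ch in seq_len(n_ch))
      d[e, ch, ] <- fill(e, ch, t)
  })
  epoch_set(d, labels, condition, modality, 1L, sfreq, t0)
}

# random multi-task problem with a shared sparse support
make_shared_tasks <- function(n_tasks = 4L, n = 30L, p = 20L, support = 1:3,
                              signal = 2, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_tasks), function(i) {
      X <- matrix(stats::rnorm(n * p), n, p)
      w <- numeric(p)
      w[support] <- signal * (1 + 0.2 * stats::rnorm(length(support)))
      y <- ifelse(stats::runif(n) < stats::plogis(X %*% w), 1L, -1L)
      if (length(unique(y)) < 2L) y[1:2] <- c(1L, -1L)
      list(x = X, y = as.integer(y), subject_id = i)
    })
  })
}
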