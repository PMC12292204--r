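# Shared fixtures, built in code.

# Small model configuration used across model/interpretation tests.
tiny_config <- function(...) {
  model_config(n_channels = 4L, n_samples = 32L, spatial_filters = 4L,
               temporal_kernel_len = 8L, depth_multiplier = 2L,
               init_seed = 7L, ...)
}

# Linearly separable toy problem: class 1 carries a strong 10 Hz sinusoid
# on channel 1, class 2 on channel 3, over weak white noise.
make_separable_toy <- function(n_per_class = 100L, snr_amp = 6, noise = 1,
                               seed = 42L, n_channels = 4L,
                               n_samples = 32L, fs = 250) {
  n <- 2L * n_per_class
  tt <- (seq_len(n_samples) - 1) / fs
  withr_seed <- function(code) eegsep:::with_seed(seed, code)
  withr_seed({
    x <- array(stats::rnorm(n_channels * n_samples * n, sd = noise),
               c(n_channels, n_samples, n))
    y <- rep(c(1L, 2L), each = n_per_class)
    for (i in seq_len(n)) {
      ch <- if (y[i] == 1L) 1L else 3L
      ph <- stats::runif(1, 0, 2 * pi)
      x[ch, , i] <- x[ch, , i] + snr_amp * sin(2 * pi * 10 * tt + ph)
    }
    list(x = x, y = factor(c("a", "b")[y]))
  })
}

# Cached toy fit so several tests can reuse one trained model.
toy_fit_cache <- new.env()
toy_fit <- function() {
  if (is.null(toy_fit_cache$fit)) {
    toy <- make_separable_toy(100L)
    idx <- seq(1, 200, by = 5)          # 40 validation trials
    toy_fit_cache$toy <- toy
    toy_fit_cache$train_idx <- setdiff(seq_len(200), idx)
    toy_fit_cache$fit <- eegcnn(
      toy$x[, , -idx], toy$y[-idx], toy$x[, , idx], toy$y[idx],
      config = tiny_config(),
      control = train_control(batch_size = 64L, max_epochs = 50L,
                              patience = 50L, restore_best = FALSE),
      seed = 5L)
  }
  toy_fit_cache
}

# O(n^2) pairwise ROC AUC oracle (ties count one half).
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force forward oracle for the two convolution stages.
conv_stages_oracle <- function(params, epoch) {
  cfg <- params$config
  S <- cfg$spatial_filters; D <- cfg$depth_multiplier
  L <- cfg$temporal_kernel_len; Tn <- cfg$n_samples
  Tp <- Tn - L + 1L
  demixed <- matrix(0, S, Tn)
  for (s in seq_len(S)) {
    for (t in seq_len(Tn)) {
      acc <- if (is.null(params$pointwise_bias)) 0 else params$pointwise_bias[s]
      for (c in seq_len(cfg$n_channels)) {
        acc <- acc + params$pointwise[s, c] * epoch[c, t]
      }
      demixed[s, t] <- acc
    }
  }
  conv <- matrix(0, S * D, Tp)
  for (m in seq_len(S * D)) {
    s <- (m - 1L) %/% D + 1L
    for (t in seq_len(Tp)) {
      acc <- 0
      for (l in seq_len(L)) acc <- acc + params$depthwise[l, m] * demixed[s, t + l - 1L]
      conv[m, t] <- acc
    }
  }
  list(demixed = demixed, conv = conv)
}

# Minimal cohort-like object carrying only a subject table (for split
# tests that never touch signal).
subjects_only_cohort <- function(n_a = 8L, n_b = 8L,
                                 groups = c("N", "A+P-")) {
  subj <- data.frame(
    subject = c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b))),
    group = rep(groups, c(n_a, n_b)), stringsAsFactors = FALSE)
  structure(list(subjects = subj, meta = data.frame(
    subject = subj$subject, group = subj$group, task = "MSIT",
    stringsAsFactors = FALSE)), class = "eeg_cohort")
}
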