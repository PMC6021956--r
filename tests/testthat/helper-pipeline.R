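# Shared fixtures: small configurations and a memoised multi-subject study.
# Everything is generated in code; nothing is read from disk.

# A desk-scale configuration: default effect sizes and noise, but EEG
# simulated directly at the 100 Hz analysis rate and short pre/post rests,
# so a full subject (simulate + preprocess + evaluate) stays in seconds.
quick_config <- function(seed, ...) {
  sim_config(seed = seed, fs_eeg = 100, pre_rest_s = 15, post_rest_s = 15, ...)
}

# A tiny two-session configuration for structural tests.
tiny_config <- function(seed = 7, n_sessions = 2, ...) {
  sim_config(seed = seed, n_sessions = n_sessions, n_trials_per_class = 3,
             fs_eeg = 100, pre_rest_s = 8, post_rest_s = 8, ...)
}

make_trials <- function(cfg) preprocess_dataset(simulate_dataset(cfg))

# Constant-covariance epochs: trials whose empirical channel covariance over
# the whole epoch equals `C` exactly (QR construction).
epochs_with_cov <- function(C, n_trials, fs = 50, span = c(0, 2),
                            labels = NULL) {
  d <- nrow(C)
  nsamp <- round(diff(span) * fs) + 1
  R <- chol(C)
  data <- array(0, c(n_trials, d, nsamp))
  for (i in seq_len(n_trials)) {
    A <- matrix(stats::rnorm(nsamp * d), nsamp, d)
    A <- sweep(A, 2, colMeans(A))
    Q <- qr.Q(qr(A))
    data[i, , ] <- t(Q %*% (sqrt(nsamp - 1) * R))
  }
  epoch_set(data, fs, seq(span[1], span[2], by = 1 / fs)[seq_len(nsamp)],
            labels %||% rep("A", n_trials), rep(0L, n_trials), "EEG",
            paste0("ch", seq_len(d)))
}

random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) / d + diag(0.1, d)
}

# Memoised per-seed study results shared by the end-to-end acceptance tests
# (offline + pseudo-online on the same preprocessed subject).
.study_cache <- new.env(parent = emptyenv())

subject_result <- function(seed, null_effects = FALSE) {
  key <- paste0("s", seed, if (null_effects) "_null")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- if (null_effects)
    quick_config(seed,
                 erd_depth = list(MA = c(theta = 0, alpha = 0, beta = 0),
                                  WC = c(theta = 0, alpha = 0, beta = 0),
                                  BL = c(theta = 0, alpha = 0, beta = 0)),
                 ers_gain = list(MA = c(theta = 0, alpha = 0, beta = 0),
                                 WC = c(theta = 0, alpha = 0, beta = 0),
                                 BL = c(theta = 0, alpha = 0, beta = 0)),
                 hrf_amp = list(MA = rep(0, 9), WC = rep(0, 9),
                                BL = rep(0, 9)))
  else quick_config(seed)
  trials <- make_trials(cfg)
  off <- crossvalidate_offline(trials, c("MA", "BL"), repetitions = 2,
                               folds = 5, seed = seed)
  res <- list(offline = summary(off))
  if (!null_effects)
    res$pseudo <- summary(pseudo_online(trials, c("MA", "BL")))
  .study_cache[[key]] <- res
  res
}

study_accuracy <- function(seeds = 0:9, what = "offline",
                           null_effects = FALSE) {
  acc <- sapply(seeds, function(s) {
    r <- subject_result(s, null_effects)[[what]]
    stats::setNames(r$mean_accuracy, r$modality)
  })
  t(acc)  # subjects x modalities
}

# Single-channel oscillation epochs whose amplitude halves during the task
# window; used by the time-frequency checks.
make_osc_epochs <- function(n_trials, fs = 100, f0 = 10, halve = TRUE,
                            seed = 1) {
  set.seed(seed)
  k <- round(-5 * fs):(round(-5 * fs) + round(10 * fs))
  time <- k / fs
  data <- array(0, c(n_trials, 1, length(time)))
  for (i in seq_len(n_trials)) {
    amp <- ifelse(halve & time >= 0 & time <= 5, 0.5, 1)
    data[i, 1, ] <- amp * sin(2 * pi * f0 * time + stats::runif(1, 0, 2 * pi)) +
      0.05 * stats::rnorm(length(time))
  }
  epoch_set(data, fs, time, rep("MA", n_trials), rep(0L, n_trials), "EEG", "Cz")
}
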