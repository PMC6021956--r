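# Evaluation: offline repeated cross-validation, session-wise pseudo-online
# splits, learning curves, information transfer rate, modality statistics and
# descriptive time-frequency maps.

MODALITIES <- c("EEG", "NIRS", "hBCI")

# Precompute everything that does not depend on the train/test split for a
# given class pair: band-filtered per-trial covariances (EEG) and the
# per-trial NIRS feature matrices.
prepare_pair <- function(trials, pair, spec = feature_spec(),
                         modalities = MODALITIES) {
  stopifnot(inherits(trials, "bci_trials"), length(pair) == 2)
  idx <- which(trials$eeg$labels %in% pair)
  if (length(idx) == 0)
    stop_hbci("no trials with the requested labels", "hbci_config_error")
  eeg <- subset_epochs(trials$eeg, idx)
  need_eeg <- any(c("EEG", "hBCI") %in% modalities)
  need_nirs <- any(c("NIRS", "hBCI") %in% modalities)
  covs <- NULL
  if (need_eeg) {
    bands <- filter_bank(eeg, spec)
    covs <- lapply(bands, trial_covariances, window = spec$eeg_window)
  }
  nf <- if (need_nirs)
    nirs_features(subset_epochs(trials$hbo, idx),
                  subset_epochs(trials$hbr, idx), spec)
  else list(hbo = NULL, hbr = NULL)
  list(pair = pair, spec = spec, labels = eeg$labels,
       session_ids = eeg$session_ids, covs = covs,
       hbo = nf$hbo, hbr = nf$hbr, orig = idx,
       channel_labels = eeg$channel_labels)
}

sub_covs <- function(covs, idx) lapply(covs, function(a) a[idx, , , drop = FALSE])

eeg_feature_matrix <- function(prep, models, idx) {
  vals <- csp_features_cov(sub_covs(prep$covs, idx), models)
  feature_matrix(vals, prep$labels[idx], prep$session_ids[idx], colnames(vals))
}

# Fit on the training trials, predict the test trials; returns a named list
# of predicted labels (character) per modality. All models, including the
# band-wise CSP filters, are fitted on training trials only.
eval_split <- function(prep, tr, te, inner_folds = 5,
                       modalities = MODALITIES) {
  spec <- prep$spec; pair <- prep$pair
  out <- list()
  if (any(c("EEG", "hBCI") %in% modalities)) {
    models <- lapply(prep$covs, function(a)
      fit_csp_cov(a[tr, , , drop = FALSE], prep$labels[tr], pair,
                  csp_pairs = spec$csp_pairs,
                  channel_labels = prep$channel_labels))
    fm_eeg_tr <- eeg_feature_matrix(prep, models, tr)
    fm_eeg_te <- eeg_feature_matrix(prep, models, te)
  }
  if ("EEG" %in% modalities) {
    m <- fit_slda(fm_eeg_tr, pair)
    out$EEG <- predict(m, fm_eeg_te)$label
  }
  if (any(c("NIRS", "hBCI") %in% modalities)) {
    hb_tr <- list(HbR = subset_features(prep$hbr, tr),
                  HbO = subset_features(prep$hbo, tr))
    hb_te <- list(HbR = subset_features(prep$hbr, te),
                  HbO = subset_features(prep$hbo, te))
  }
  if ("NIRS" %in% modalities) {
    m <- fit_meta(hb_tr, pair, inner_folds = inner_folds)
    out$NIRS <- predict(m, hb_te)$label
  }
  if ("hBCI" %in% modalities) {
    m <- fit_meta(c(list(EEG = fm_eeg_tr), hb_tr), pair,
                  inner_folds = inner_folds)
    out$hBCI <- predict(m, c(list(EEG = fm_eeg_te), hb_te))$label
  }
  out
}

cv_result <- function(mode, modality, pair, accuracies, predictions) {
  structure(list(mode = mode, modality = modality, pair = pair,
                 accuracies = accuracies, predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s %s (%s vs %s): accuracy %.3f +/- %.3f\n",
              x$mode, x$modality, x$pair[1], x$pair[2],
              mean(x$accuracies), stats::sd(as.numeric(x$accuracies))))
  invisible(x)
}

#' Mean accuracy of a cross-validation result
#' @param x a `cv_result`.
#' @return scalar mean accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(x) mean(x$accuracies)

bci_eval <- function(results, mode, pair) {
  structure(list(results = results, mode = mode, pair = pair),
            class = "bci_eval")
}

#' @export
print.bci_eval <- function(x, ...) {
  cat(sprintf("<bci_eval> %s, %s vs %s\n", x$mode, x$pair[1], x$pair[2]))
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
summary.bci_eval <- function(object, ...) {
  data.frame(modality = names(object$results),
             mean_accuracy = vapply(object$results, cv_accuracy, 0),
             sd = vapply(object$results, function(r)
               stats::sd(as.numeric(r$accuracies)), 0),
             row.names = NULL)
}

#' Offline repeated stratified cross-validation
#'
#' Repeated k-fold evaluation of the EEG classifier (filter-bank CSP +
#' shrinkage LDA), the NIRS meta classifier (HbR + HbO) and the hybrid meta
#' classifier (EEG + HbR + HbO). Folds are stratified by class; all spatial
#' filters and classifiers are refit inside every training fold.
#'
#' @param trials a [preprocess_dataset()] result.
#' @param pair ordered class pair, e.g. `c("MA", "BL")`.
#' @param spec a [feature_spec()].
#' @param repetitions,folds cross-validation scheme (default 10 x 5).
#' @param seed RNG seed for the fold assignments.
#' @param inner_folds inner folds of the meta layer.
#' @param modalities subset of `c("EEG", "NIRS", "hBCI")`.
#' @return a `bci_eval` object; per-modality accuracy matrices are
#'   `repetitions x folds`.
#' @export
crossvalidate_offline <- function(trials, pair, spec = feature_spec(),
                                  repetitions = 10, folds = 5, seed = 1,
                                  inner_folds = 5, modalities = MODALITIES) {
  prep <- prepare_pair(trials, pair, spec, modalities)
  counts <- table(prep$labels)
  if (min(counts) < folds)
    stop_hbci("fewer trials per class than folds: stratification impossible",
              "hbci_config_error")
  acc <- lapply(modalities, function(m) matrix(0, repetitions, folds))
  names(acc) <- modalities
  preds <- list()
  with_seed(seed, {
    for (rep_i in seq_len(repetitions)) {
      fold <- stratified_folds(prep$labels, folds)
      for (f in seq_len(folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        p <- eval_split(prep, tr, te, inner_folds, modalities)
        for (m in modalities) {
          acc[[m]][rep_i, f] <- mean(p[[m]] == prep$labels[te])
          preds[[length(preds) + 1L]] <-
            data.frame(modality = m, repetition = rep_i, fold = f,
                       trial = prep$orig[te], true = prep$labels[te], pred = p[[m]])
        }
      }
    }
  })
  preds <- do.call(rbind, preds)
  results <- lapply(modalities, function(m)
    cv_result("offline", m, pair, acc[[m]],
              preds[preds$modality == m, ]))
  names(results) <- modalities
  bci_eval(results, "offline", pair)
}

#' Session-wise pseudo-online evaluation
#'
#' `"causal"` mode trains on all sessions but the last and tests on the last
#' (chronological split emulating online use); `"session_cv"` performs
#' leave-one-session-out so no test set shares a session with its training
#' set.
#'
#' @inheritParams crossvalidate_offline
#' @param mode `"causal"` (default) or `"session_cv"`.
#' @return a `bci_eval` object; accuracies have one entry per test session.
#' @export
pseudo_online <- function(trials, pair, mode = c("causal", "session_cv"),
                          spec = feature_spec(), inner_folds = 5,
                          modalities = MODALITIES) {
  mode <- match.arg(mode)
  prep <- prepare_pair(trials, pair, spec, modalities)
  sessions <- sort(unique(prep$session_ids))
  if (length(sessions) < 2)
    stop_hbci("pseudo-online evaluation requires at least 2 sessions",
              "hbci_config_error")
  test_sets <- if (mode == "causal") list(max(sessions)) else as.list(sessions)
  acc <- lapply(modalities, function(m) numeric(length(test_sets)))
  names(acc) <- modalities
  preds <- list()
  for (k in seq_along(test_sets)) {
    te <- which(prep$session_ids == test_sets[[k]])
    tr <- if (mode == "causal") which(prep$session_ids != test_sets[[k]] &
                                        prep$session_ids < test_sets[[k]])
    else which(prep$session_ids != test_sets[[k]])
    p <- eval_split(prep, tr, te, inner_folds, modalities)
    for (m in modalities) {
      acc[[m]][k] <- mean(p[[m]] == prep$labels[te])
      preds[[length(preds) + 1L]] <-
        data.frame(modality = m, repetition = 1L, fold = k,
                   trial = prep$orig[te],
                   true = prep$labels[te], pred = p[[m]])
    }
  }
  preds <- do.call(rbind, preds)
  results <- lapply(modalities, function(m)
    cv_result(paste0("pseudo_online_", mode), m, pair, acc[[m]],
              preds[preds$modality == m, ]))
  names(results) <- modalities
  bci_eval(results, paste0("pseudo_online_", mode), pair)
}

#' Accuracy as a function of the number of training samples
#'
#' Emulates online calibration: for each `n` in `n_grid`, draws `resamples`
#' stratified subsets of `n` trials per class from the training sessions
#' (all but the last), trains the pipeline, and tests on the last session.
#' When `n` equals the full per-class training count the (sorted) subset is
#' the whole training set and a single resample reproduces the causal
#' pseudo-online result.
#'
#' @inheritParams crossvalidate_offline
#' @param n_grid training-set sizes, in trials per class.
#' @param resamples random subsets per grid point.
#' @return object of class `learning_curve`: list with `n_grid` and an
#'   accuracy array `n x resample x modality`.
#' @export
learning_curve <- function(trials, pair, n_grid = c(5, 10, 15, 20),
                           resamples = 20, spec = feature_spec(), seed = 1,
                           inner_folds = 5, modalities = "hBCI") {
  prep <- prepare_pair(trials, pair, spec, modalities)
  sessions <- sort(unique(prep$session_ids))
  if (length(sessions) < 2)
    stop_hbci("learning curves require at least 2 sessions",
              "hbci_config_error")
  te <- which(prep$session_ids == max(sessions))
  pool <- which(prep$session_ids != max(sessions))
  per_class <- lapply(pair, function(cl) pool[prep$labels[pool] == cl])
  max_n <- min(lengths(per_class))
  if (any(n_grid < 2) || any(n_grid > max_n))
    stop_hbci(sprintf("n_grid must lie in [2, %d] trials per class", max_n),
              "hbci_parameter_error")
  acc <- array(NA_real_, c(length(n_grid), resamples, length(modalities)),
               dimnames = list(paste0("n", n_grid), NULL, modalities))
  with_seed(seed, {
    for (i in seq_along(n_grid)) {
      n <- n_grid[i]
      for (r in seq_len(resamples)) {
        tr <- sort(unlist(lapply(per_class, function(ix)
          ix[sample.int(length(ix), n)])))
        p <- eval_split(prep, tr, te, inner_folds, modalities)
        for (m in seq_along(modalities))
          acc[i, r, m] <- mean(p[[modalities[m]]] == prep$labels[te])
      }
    }
  })
  structure(list(n_grid = n_grid, accuracy = acc, pair = pair,
                 modalities = modalities), class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %s vs %s\n", x$pair[1], x$pair[2]))
  for (m in x$modalities) {
    mu <- apply(x$accuracy[, , m, drop = FALSE], 1, mean)
    sdv <- apply(x$accuracy[, , m, drop = FALSE], 1, stats::sd)
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("n=%d %.3f+/-%.3f", x$n_grid, mu, sdv),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Smallest training size reaching a target accuracy
#' @param x a [learning_curve()] result.
#' @param threshold accuracy target (default 0.70, the usual effective-BCI
#'   criterion).
#' @param modality which modality to inspect.
#' @return smallest `n` whose mean accuracy exceeds `threshold`, or `NA`.
#' @export
min_training_samples <- function(x, threshold = 0.70, modality = "hBCI") {
  mu <- apply(x$accuracy[, , modality, drop = FALSE], 1, mean)
  ok <- which(mu > threshold)
  if (length(ok)) x$n_grid[min(ok)] else NA_integer_
}

#' Information transfer rate
#'
#' Wolpaw's per-decision bit rate scaled to bits per minute:
#' `ITR = m (log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1)))` with
#' `m = 60 / trial_len_s` decisions per minute and the convention
#' `0 log2 0 = 0`.
#'
#' @param P classification accuracy in `(0, 1]` (vectorized).
#' @param N number of available commands (>= 2).
#' @param trial_len_s decision time per trial in seconds (default 5).
#' @return object of class `itr_result` with `P`, `N`, `m`, `bits_per_min`.
#' @export
itr <- function(P, N = 2, trial_len_s = 5) {
  if (any(P <= 0) || any(P > 1))
    stop_hbci("accuracy P must lie in (0, 1]", "hbci_domain_error")
  if (N < 2) stop_hbci("N must be >= 2", "hbci_domain_error")
  assert_scalar_num(trial_len_s, "trial_len_s", lo = 1e-9)
  m <- 60 / trial_len_s
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits_per_trial <- log2(N) + plog(P) + ifelse(P < 1,
                                               (1 - P) * log2((1 - P) / (N - 1)),
                                               0)
  structure(list(P = P, N = N, m = m, trial_len_s = trial_len_s,
                 bits_per_min = m * bits_per_trial),
            class = "itr_result")
}

#' @export
print.itr_result <- function(x, ...) {
  cat(sprintf("<itr> P = %s, N = %d, m = %g/min -> %s bits/min\n",
              paste(sprintf("%.3f", x$P), collapse = ", "), x$N, x$m,
              paste(sprintf("%.3f", x$bits_per_min), collapse = ", ")))
  invisible(x)
}

#' Theoretical chance level from the exact binomial distribution
#'
#' Smallest accuracy `k/n` whose one-sided exact binomial tail probability
#' under random guessing (p = 0.5) is below `alpha`. For 60 trials at
#' alpha = 0.05 the threshold is 37/60 (about 61.7%).
#'
#' @param n_trials number of test trials.
#' @param alpha significance level; `alpha >= 1` returns 0 (any accuracy
#'   passes).
#' @return accuracy threshold in `[0, 1]`.
#' @export
chance_level <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1)
  if (alpha >= 1) return(0)
  for (k in 0:(n_trials + 1)) {
    tail <- 1 - stats::pbinom(k - 1, n_trials, 0.5)
    if (tail < alpha) return(min(k / n_trials, 1))
  }
  1
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment used for the post-hoc pairwise comparisons; e.g.
#' raw p-values (0.01, 0.02, 0.04) become (0.03, 0.03, 0.04).
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values (monotone, `>=` raw).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Compare modality accuracies across subjects
#'
#' Friedman omnibus test over the (subjects x modalities) accuracy table,
#' followed by pairwise Wilcoxon signed-rank tests (exact for n <= 25) with
#' Benjamini-Hochberg false-discovery-rate adjustment.
#'
#' @param acc_table numeric matrix or data.frame, subjects x conditions
#'   (>= 3 subjects, >= 2 conditions; typically EEG, NIRS, hBCI).
#' @return object of class `stats_report`.
#' @export
compare_modalities <- function(acc_table) {
  M <- as.matrix(acc_table)
  if (nrow(M) < 3 || ncol(M) < 2)
    stop_hbci("need >= 3 subjects and >= 2 conditions", "hbci_parameter_error")
  if (is.null(colnames(M))) colnames(M) <- paste0("cond", seq_len(ncol(M)))
  if (any(apply(M, 2, stats::sd) == 0))
    warning("constant column(s): tests are degenerate")
  fr <- suppressWarnings(stats::friedman.test(M))
  if (!is.finite(fr$statistic)) {  # complete ties (e.g. identical columns)
    fr$statistic <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(colnames(M), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    x <- M[, pr[1]]; y <- M[, pr[2]]
    if (all(x == y)) return(1)
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        exact = nrow(M) <= 25,
                                        correct = TRUE)$p.value)
  })
  rep <- list(friedman = list(statistic = unname(fr$statistic),
                              p_value = fr$p.value),
              pairwise = data.frame(a = pairs[1, ], b = pairs[2, ],
                                    p_raw = p_raw,
                                    p_adj = fdr_adjust(p_raw)),
              means = colMeans(M), sds = apply(M, 2, stats::sd))
  class(rep) <- "stats_report"
  rep
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> Friedman chi2 = %.3f, p = %.4g\n",
              x$friedman$statistic, x$friedman$p_value))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: p = %.4g (BH-adjusted %.4g)\n",
                x$pairwise$a[i], x$pairwise$b[i], x$pairwise$p_raw[i],
                x$pairwise$p_adj[i]))
  invisible(x)
}

#' Event-related spectral perturbation maps
#'
#' Hann-tapered sliding-window power spectra (zero-padded by `pad_ratio`),
#' averaged over trials of each class and over the selected channels, then
#' expressed in dB relative to the per-frequency geometric mean over the
#' baseline interval (so the baseline rows average to 0 dB exactly).
#' Class-difference maps are dB subtractions.
#'
#' @param epochs an EEG [epoch_set()].
#' @param window_ms sliding window length (default 5120 ms).
#' @param step_ms sliding step (default 80 ms).
#' @param pad_ratio zero-padding factor (2 halves the frequency spacing).
#' @param baseline baseline interval in seconds (window centers inside it
#'   define the reference spectrum).
#' @param channels channel names or indices to average (default all).
#' @param diff_vs label of the reference class for difference maps (default
#'   `"BL"` when present).
#' @return list with `maps` (per class, objects of class `tf_map` with
#'   `times`, `freqs`, `values` [freq x time, dB]) and `diffs`.
#' @export
ersp <- function(epochs, window_ms = 5120, step_ms = 80, pad_ratio = 2,
                 baseline = c(-5, -2), channels = NULL, diff_vs = "BL") {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  wlen <- round(window_ms / 1000 * fs)
  nsamp <- dim(epochs$data)[3]
  if (wlen >= nsamp)
    stop_hbci("window must be shorter than the epoch", "hbci_parameter_error")
  step <- max(1L, round(step_ms / 1000 * fs))
  ch <- if (is.null(channels)) seq_along(epochs$channel_labels)
  else if (is.character(channels)) match(channels, epochs$channel_labels)
  else channels
  starts <- seq(1L, nsamp - wlen + 1L, by = step)
  centers <- epochs$time[starts + floor(wlen / 2)]
  nfft <- wlen * pad_ratio
  nf <- nfft %/% 2 + 1L
  freqs <- (seq_len(nf) - 1) * fs / nfft
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = wlen))
  base_idx <- which(centers >= baseline[1] - 1e-9 & centers <= baseline[2] + 1e-9)
  if (!length(base_idx))
    stop_hbci("no window centers inside the baseline interval",
              "hbci_parameter_error")
  classes <- unique(epochs$labels)
  maps <- list()
  for (cl in classes) {
    tri <- which(epochs$labels == cl)
    P <- matrix(0, nf, length(starts))
    for (i in tri) for (c in ch) {
      x <- epochs$data[i, c, ]
      for (s in seq_along(starts)) {
        seg <- x[starts[s]:(starts[s] + wlen - 1L)] * taper
        sp <- abs(stats::fft(c(seg, numeric(nfft - wlen))))^2
        P[, s] <- P[, s] + sp[seq_len(nf)]
      }
    }
    P <- P / (length(tri) * length(ch))
    ref <- exp(rowMeans(log(pmax(P[, base_idx, drop = FALSE], 1e-300))))
    vals <- 10 * log10(P / ref)
    maps[[cl]] <- structure(list(times = centers, freqs = freqs, values = vals,
                                 window_ms = window_ms, step_ms = step_ms,
                                 pad_ratio = pad_ratio, class = cl),
                            class = "tf_map")
  }
  diffs <- list()
  if (!is.null(diff_vs) && diff_vs %in% classes) {
    for (cl in setdiff(classes, diff_vs)) {
      d <- maps[[cl]]
      d$values <- maps[[cl]]$values - maps[[diff_vs]]$values
      d$class <- paste0(cl, "-", diff_vs)
      diffs[[d$class]] <- d
    }
  }
  list(maps = maps, diffs = diffs)
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %s: %d freqs x %d times, window %g ms / step %g ms / pad %g\n",
              x$class, length(x$freqs), length(x$times), x$window_ms,
              x$step_ms, x$pad_ratio))
  invisible(x)
}

#' @export
plot.tf_map <- function(x, flim = c(2, 35), zlim = NULL, ...) {
  fi <- x$freqs >= flim[1] & x$freqs <= flim[2]
  graphics::image(x$times, x$freqs[fi], t(x$values[fi, , drop = FALSE]),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = paste("ERD/S:", x$class), zlim = zlim, ...)
  graphics::abline(v = c(0, 5), lty = 2)
  invisible(x)
}
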