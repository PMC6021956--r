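#' Feature extraction specification
#'
#' @param eeg_bands named list of band edges in Hz (defaults: theta 4-8,
#'   alpha 8-13, beta 13-30).
#' @param csp_pairs number of spatial-filter pairs retained per band (first
#'   and last `csp_pairs` eigenvectors; default 3, giving 6 components).
#' @param eeg_window EEG analysis window in seconds (task period 0-5 s).
#' @param nirs_windows list of sub-windows in seconds (defaults 0-2, 2-4,
#'   4-5 s); each window is half-open `[t0, t1)` except the last, which is
#'   closed so the windows partition the task period exactly.
#' @param nirs_stats statistics per window: `"mean"` and/or `"slope"`.
#' @param slope_method `"lsfit"` (least-squares linear coefficient, default)
#'   or `"endpoint"` (last minus first over duration).
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(eeg_bands = list(theta = c(4, 8), alpha = c(8, 13),
                                          beta = c(13, 30)),
                         csp_pairs = 3, eeg_window = c(0, 5),
                         nirs_windows = list(c(0, 2), c(2, 4), c(4, 5)),
                         nirs_stats = c("mean", "slope"),
                         slope_method = c("lsfit", "endpoint")) {
  slope_method <- match.arg(slope_method)
  structure(list(eeg_bands = eeg_bands, csp_pairs = csp_pairs,
                 eeg_window = eeg_window, nirs_windows = nirs_windows,
                 nirs_stats = nirs_stats, slope_method = slope_method),
            class = "feature_spec")
}

#' Feature matrix
#'
#' @param values numeric matrix, trials x features.
#' @param labels trial labels.
#' @param session_ids per-trial session ids.
#' @param feature_names column names.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, session_ids, feature_names) {
  stopifnot(is.matrix(values), nrow(values) == length(labels),
            ncol(values) == length(feature_names))
  if (any(!is.finite(values)))
    stop_hbci("feature matrix contains non-finite values", "hbci_feature_error")
  colnames(values) <- feature_names
  structure(list(values = values, labels = as.character(labels),
                 session_ids = as.integer(session_ids),
                 feature_names = feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a feature matrix by trial index
#' @param x a [feature_matrix()].
#' @param idx trial indices.
#' @return the subset `feature_matrix`.
#' @export
subset_features <- function(x, idx) {
  feature_matrix(x$values[idx, , drop = FALSE], x$labels[idx],
                 x$session_ids[idx], x$feature_names)
}

#' Band-filter epochs into a filter bank
#'
#' Zero-phase Butterworth band-pass of every epoch, one copy per band.
#'
#' @param epochs an EEG [epoch_set()].
#' @param spec a [feature_spec()].
#' @return named list of band-filtered `epoch_set`s.
#' @export
filter_bank <- function(epochs, spec = feature_spec()) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- list()
  nyq <- epochs$fs / 2
  for (b in names(spec$eeg_bands)) {
    band <- spec$eeg_bands[[b]]
    if (band[2] >= nyq)
      stop_hbci(sprintf("band %s exceeds the Nyquist frequency", b),
                "hbci_parameter_error")
    # 6-pole bandpass: neighbouring default bands are separated by >= 20 dB
    # after the forward-backward pass
    bf <- signal::butter(3, band / nyq, type = "pass")
    es <- epochs
    for (i in seq_len(dim(epochs$data)[1]))
      for (c in seq_len(dim(epochs$data)[2]))
        es$data[i, c, ] <- signal::filtfilt(bf, epochs$data[i, c, ])
    out[[b]] <- es
  }
  out
}

# Per-trial channel covariance over a time window; returns an array
# (trial, channel, channel) of centered covariances (divisor n-1).
trial_covariances <- function(epochs, window) {
  eps <- 1e-9
  mask <- epochs$time >= window[1] - eps & epochs$time <= window[2] + eps
  nt <- dim(epochs$data)[1]; nc <- dim(epochs$data)[2]
  covs <- array(0, c(nt, nc, nc))
  for (i in seq_len(nt)) {
    X <- t(epochs$data[i, , mask])  # samples x channels
    covs[i, , ] <- stats::cov(X)
  }
  covs
}

# Core CSP solver on two averaged class covariances. Solves the generalized
# eigenproblem C1 w = lambda (C1 + C2) w via whitening of the pooled
# covariance; eigenvalues lie in [0, 1], sorted descending; column signs are
# fixed so the largest-magnitude entry of each filter is positive.
csp_solve <- function(C1, C2, reg = 1e-9) {
  d <- nrow(C1)
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (min(ec$values) < tol) {
    warning("rank-deficient pooled covariance; applying diagonal regularization")
    Cc <- Cc + diag(reg * sum(diag(Cc)) / d, d)
    ec <- eigen(Cc, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values), d) %*% t(ec$vectors)  # whitener
  S <- P %*% C1 %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W <- t(P) %*% es$vectors  # columns are spatial filters
  for (j in seq_len(d)) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, eigenvalues = es$values)
}

#' Fit common spatial patterns for one band
#'
#' Trial covariances are trace-normalized, averaged per class, and jointly
#' diagonalized: the returned filters `W` satisfy `t(W) (C1 + C2) W = I` and
#' `t(W) C1 W = diag(eigenvalues)` with eigenvalues in `[0, 1]` sorted
#' descending (large eigenvalue = more class-1 variance).
#'
#' @param epochs an [epoch_set()] containing exactly the two classes of
#'   `class_pair` (other trials are ignored).
#' @param class_pair ordered pair of labels.
#' @param window analysis window in seconds.
#' @param csp_pairs filter pairs to mark as selected.
#' @return an object of class `csp_model` with `W`, `eigenvalues`,
#'   `selected`, `class_pair`, `channel_labels`.
#' @export
fit_csp <- function(epochs, class_pair, window = c(0, 5), csp_pairs = 3) {
  stopifnot(inherits(epochs, "epoch_set"), length(class_pair) == 2)
  idx <- epochs$labels %in% class_pair
  covs <- trial_covariances(subset_epochs(epochs, which(idx)), window)
  labels <- epochs$labels[idx]
  fit_csp_cov(covs, labels, class_pair, csp_pairs,
              channel_labels = epochs$channel_labels)
}

# CSP from precomputed per-trial covariances (fast path used by the
# cross-validation drivers).
fit_csp_cov <- function(covs, labels, class_pair, csp_pairs = 3,
                        channel_labels = NULL) {
  if (sum(labels == class_pair[1]) < 2 || sum(labels == class_pair[2]) < 2)
    stop_hbci("need >= 2 trials per class to fit CSP", "hbci_training_error")
  d <- dim(covs)[2]
  if (2 * csp_pairs > d)
    stop_hbci("csp_pairs x 2 exceeds the channel count", "hbci_config_error")
  avg_class <- function(cl) {
    idx <- which(labels == cl)
    M <- matrix(0, d, d)
    for (i in idx) {
      Ci <- covs[i, , ]
      M <- M + Ci / sum(diag(Ci))
    }
    M / length(idx)
  }
  sol <- csp_solve(avg_class(class_pair[1]), avg_class(class_pair[2]))
  sel <- c(seq_len(csp_pairs), d - csp_pairs + seq_len(csp_pairs))
  structure(list(W = sol$W, eigenvalues = sol$eigenvalues, selected = sel,
                 class_pair = class_pair,
                 channel_labels = channel_labels %||% paste0("ch", seq_len(d))),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %s vs %s, %d channels, eigenvalues %s\n",
              x$class_pair[1], x$class_pair[2], nrow(x$W),
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

# Log-variance of the selected CSP projections from precomputed covariances.
csp_features_cov <- function(covs, models) {
  blocks <- lapply(names(models), function(b) {
    m <- models[[b]]
    W6 <- m$W[, m$selected, drop = FALSE]
    nt <- dim(covs[[b]])[1]
    f <- matrix(0, nt, ncol(W6))
    for (i in seq_len(nt))
      f[i, ] <- log(pmax(diag(t(W6) %*% covs[[b]][i, , ] %*% W6), 1e-300))
    colnames(f) <- paste0(b, ".csp", m$selected)
    f
  })
  do.call(cbind, blocks)
}

#' Filter-bank CSP log-variance features
#'
#' Projects every trial onto the selected spatial filters of each band's
#' model and takes the log of the projected variance over the analysis
#' window; features are concatenated across bands
#' (default 3 bands x 6 components = 18).
#'
#' @param band_epochs named list of band-filtered [epoch_set()]s
#'   (from [filter_bank()]).
#' @param models named list of [fit_csp()] models (same band names).
#' @param spec a [feature_spec()].
#' @return a [feature_matrix()].
#' @export
csp_features <- function(band_epochs, models, spec = feature_spec()) {
  stopifnot(identical(sort(names(band_epochs)), sort(names(models))))
  first <- band_epochs[[1]]
  for (b in names(models))
    if (!identical(band_epochs[[b]]$channel_labels, models[[b]]$channel_labels))
      stop_hbci("channel set differs between epochs and CSP model",
                "hbci_config_error")
  covs <- lapply(band_epochs, trial_covariances, window = spec$eeg_window)
  names(covs) <- names(band_epochs)
  vals <- csp_features_cov(covs[names(models)], models)
  feature_matrix(vals, first$labels, first$session_ids, colnames(vals))
}

# Window masks: half-open [t0, t1) except the last window, closed at its end.
nirs_window_mask <- function(time, windows, w) {
  eps <- 1e-9
  t0 <- windows[[w]][1]; t1 <- windows[[w]][2]
  if (w == length(windows))
    time >= t0 - eps & time <= t1 + eps
  else
    time >= t0 - eps & time < t1 - eps
}

#' Windowed mean and slope features from chromophore epochs
#'
#' Per chromophore, channel and sub-window: the mean concentration change and
#' the least-squares slope (mol/L/s) of the time course. The default spec
#' yields 9 channels x 3 windows x 2 statistics = 54 features per
#' chromophore.
#'
#' @param hbo,hbr [epoch_set()]s with aligned trials.
#' @param spec a [feature_spec()].
#' @return list with `hbo` and `hbr` [feature_matrix()]s.
#' @export
nirs_features <- function(hbo, hbr, spec = feature_spec()) {
  stopifnot(identical(hbo$labels, hbr$labels))
  one <- function(es) {
    nt <- dim(es$data)[1]; nc <- dim(es$data)[2]
    nw <- length(spec$nirs_windows)
    cols <- list(); names_out <- character(0)
    for (w in seq_len(nw)) {
      mask <- nirs_window_mask(es$time, spec$nirs_windows, w)
      if (sum(mask) < 2)
        stop_hbci("sub-window has fewer than 2 samples (slope undefined)",
                  "hbci_parameter_error")
      tt <- es$time[mask]
      tc <- tt - mean(tt)
      denom <- sum(tc^2)
      wname <- sprintf("w%g_%g", spec$nirs_windows[[w]][1],
                       spec$nirs_windows[[w]][2])
      for (stat in spec$nirs_stats) {
        f <- matrix(0, nt, nc)
        for (i in seq_len(nt)) {
          Y <- es$data[i, , mask, drop = FALSE][1, , , drop = TRUE]
          if (is.null(dim(Y))) Y <- matrix(Y, nrow = nc)
          if (stat == "mean") f[i, ] <- rowMeans(Y)
          else if (spec$slope_method == "lsfit")
            f[i, ] <- as.numeric(Y %*% tc) / denom
          else f[i, ] <- (Y[, ncol(Y)] - Y[, 1]) / (tt[length(tt)] - tt[1])
        }
        cols[[length(cols) + 1L]] <- f
        names_out <- c(names_out, paste0(es$channel_labels, ".", wname, ".", stat))
      }
    }
    feature_matrix(do.call(cbind, cols), es$labels, es$session_ids, names_out)
  }
  list(hbo = one(hbo), hbr = one(hbr))
}
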