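#' Optical constants for the modified Beer-Lambert law
#'
#' Houses the wavelengths, molar extinction coefficients, source-detector
#' separation and differential pathlength factors used to convert optical
#' density changes into chromophore concentration changes. Defaults use
#' 760/850 nm, published extinction coefficients (1/(mol/L x cm)), a 3.0 cm
#' separation and a DPF of 6.0 at both wavelengths.
#'
#' @param wavelengths two wavelengths in nm.
#' @param extinction 2 x 2 matrix, rows = wavelengths, columns = c(HbO, HbR),
#'   in 1/(mol/L x cm).
#' @param distance_cm source-detector separation in cm.
#' @param dpf differential pathlength factor per wavelength.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(wavelengths = c(760, 850),
                          extinction = matrix(c(1486.5865, 3843.707,
                                                2526.391, 1798.643),
                                              nrow = 2, byrow = TRUE,
                                              dimnames = list(c("760", "850"),
                                                              c("HbO", "HbR"))),
                          distance_cm = 3.0, dpf = c(6.0, 6.0)) {
  stopifnot(length(wavelengths) == 2, is.matrix(extinction),
            all(dim(extinction) == 2), length(dpf) == 2)
  assert_scalar_num(distance_cm, "distance_cm", lo = 1e-9)
  if (any(dpf <= 0)) stop_hbci("dpf must be > 0", "hbci_config_error")
  if (kappa(extinction) >= 1e6)
    stop_hbci("extinction matrix is (near-)singular", "hbci_config_error")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 distance_cm = distance_cm, dpf = dpf),
            class = "optics_config")
}

# Per-wavelength linear system matrix: dOD = M %*% c(dHbO, dHbR)
mbll_matrix <- function(optics) {
  optics$extinction * optics$distance_cm * optics$dpf
}

#' Forward Beer-Lambert model: chromophore concentrations to optical density
#'
#' Inverse operation of [mbll()]; used by the generator to emit raw
#' dual-wavelength optical-density recordings.
#'
#' @param rec a `"NIRS-Hb"` [continuous_recording()] (9 HbO + 9 HbR channels).
#' @param optics an [optics_config()].
#' @return a `"NIRS-OD"` recording with channels `CHi@wl`.
#' @export
forward_mbll <- function(rec, optics = optics_config()) {
  stopifnot(rec$modality == "NIRS-Hb")
  chrom <- split_chromophores(rec)
  M <- mbll_matrix(optics)
  nch <- nrow(chrom$hbo$data)
  od <- matrix(0, 2 * nch, ncol(rec$data))
  labels <- character(2 * nch)
  for (c in seq_len(nch)) {
    conc <- rbind(chrom$hbo$data[c, ], chrom$hbr$data[c, ])
    od[2 * c - 1L, ] <- M[1, 1] * conc[1, ] + M[1, 2] * conc[2, ]
    od[2 * c, ] <- M[2, 1] * conc[1, ] + M[2, 2] * conc[2, ]
    labels[c(2 * c - 1L, 2 * c)] <-
      paste0(chrom$hbo$channel_labels[c], "@", optics$wavelengths)
  }
  continuous_recording("NIRS-OD", rec$fs, od, labels, "OD", rec$markers)
}

#' Modified Beer-Lambert law inversion
#'
#' Solves, per channel and time point, the 2 x 2 linear system
#' `dOD(lambda) = eps(lambda, HbO) dC_HbO + eps(lambda, HbR) dC_HbR) * L * DPF(lambda)`
#' for the chromophore concentration changes.
#'
#' @param od a `"NIRS-OD"` [continuous_recording()] with channel labels
#'   `CHi@wl` (two wavelengths per channel).
#' @param optics an [optics_config()].
#' @return list with `hbo` and `hbr` [continuous_recording()]s in mol/L.
#' @export
mbll <- function(od, optics = optics_config()) {
  stopifnot(od$modality == "NIRS-OD")
  base <- sub("@[0-9.]+$", "", od$channel_labels)
  wl <- sub("^.*@", "", od$channel_labels)
  chans <- unique(base)
  Minv <- solve(mbll_matrix(optics))
  n <- ncol(od$data)
  hbo <- matrix(0, length(chans), n)
  hbr <- matrix(0, length(chans), n)
  for (i in seq_along(chans)) {
    rows <- match(paste0(chans[i], "@", optics$wavelengths), od$channel_labels)
    if (any(is.na(rows)))
      stop_hbci(sprintf("channel %s lacks both wavelengths", chans[i]),
                "hbci_config_error")
    conc <- Minv %*% od$data[rows, , drop = FALSE]
    hbo[i, ] <- conc[1, ]
    hbr[i, ] <- conc[2, ]
  }
  list(hbo = continuous_recording("NIRS-Hb", od$fs, hbo, chans, "mol/L",
                                  od$markers),
       hbr = continuous_recording("NIRS-Hb", od$fs, hbr, chans, "mol/L",
                                  od$markers))
}

#' Butterworth band-pass filter a recording
#'
#' @param rec a [continuous_recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order total filter order (number of poles); must be even, the
#'   low/high prototype order is `order/2`. Default 4 for EEG; the
#'   hemodynamic filter uses `order = 6` (0.01-0.2 Hz).
#' @param zero_phase forward-backward filtering (no phase distortion) when
#'   `TRUE`, single-pass otherwise.
#' @return the filtered recording (same shape, rate and markers).
#' @export
bandpass <- function(rec, low, high, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_hbci("band edges must satisfy 0 < low < high < fs/2",
              "hbci_parameter_error")
  if (order %% 2 != 0 || order < 2)
    stop_hbci("order must be an even integer >= 2", "hbci_parameter_error")
  bf <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  out <- rec
  for (c in seq_len(nrow(rec$data))) {
    x <- rec$data[c, ]
    out$data[c, ] <- if (zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  }
  out
}

# Compact deterministic symmetric fixed-point ICA (tanh contrast), used only
# for EOG component rejection. Initialization is the identity in whitened
# space, so results are reproducible.
fast_ica <- function(X, max_iter = 200, tol = 1e-8) {
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  K <- diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  d <- nrow(Z); n <- ncol(Z)
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), d) %*% t(s$vectors) %*% W
  }
  W <- diag(d)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), d) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  pinv_K <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), d)
  list(S = W %*% Z, W = W, K = K, pinv_K = pinv_K, mean = mu)
}

#' Remove ocular artifacts from EEG
#'
#' `"regression"` subtracts the least-squares projection of every EEG channel
#' onto the EOG channels. `"ica"` decomposes the EEG with a deterministic
#' fixed-point ICA and zeroes components whose absolute correlation with any
#' EOG channel exceeds `threshold`. `"none"` returns the input unchanged
#' (the two pipelines perform comparably, so the correction is optional).
#'
#' @param eeg,eog time-aligned [continuous_recording()]s at the same rate.
#' @param method `"regression"`, `"ica"` or `"none"`.
#' @param threshold absolute-correlation cutoff for ICA component rejection.
#' @return the cleaned EEG recording.
#' @export
remove_eog <- function(eeg, eog, method = c("regression", "ica", "none"),
                       threshold = 0.7) {
  method <- match.arg(method)
  if (method == "none") return(eeg)
  if (ncol(eeg$data) != ncol(eog$data) || eeg$fs != eog$fs)
    stop_hbci("EEG and EOG recordings are not aligned (length or rate mismatch)",
              "hbci_alignment_error")
  Y <- eog$data - rowMeans(eog$data)
  if (all(abs(Y) < .Machine$double.eps)) return(eeg)
  out <- eeg
  if (method == "regression") {
    X <- eeg$data - rowMeans(eeg$data)
    B <- (X %*% t(Y)) %*% solve(tcrossprod(Y))
    out$data <- eeg$data - B %*% Y
  } else {
    ic <- fast_ica(eeg$data)
    r <- abs(stats::cor(t(ic$S), t(eog$data)))
    bad <- apply(r, 1, max) > threshold
    S <- ic$S
    S[bad, ] <- 0
    out$data <- ic$pinv_K %*% t(ic$W) %*% S + ic$mean
  }
  out
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies a zero-phase anti-aliasing FIR low-pass (cutoff 0.8 x the target
#' Nyquist frequency) and keeps every k-th sample; markers are re-indexed.
#'
#' @param rec a [continuous_recording()].
#' @param target_fs new rate; `fs / target_fs` must be an integer.
#' @param fir_order FIR filter order (Hamming-window design).
#' @return the decimated recording.
#' @export
decimate <- function(rec, target_fs, fir_order = 96) {
  stopifnot(inherits(rec, "continuous_recording"))
  k <- rec$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop_hbci("fs must be an integer multiple of target_fs",
              "hbci_parameter_error")
  k <- as.integer(round(k))
  if (k == 1L) return(rec)
  b <- signal::fir1(fir_order, 0.8 * (target_fs / 2) / (rec$fs / 2))
  keep <- seq(1L, ncol(rec$data), by = k)
  data <- matrix(0, nrow(rec$data), length(keep))
  ma <- signal::Ma(b)
  for (c in seq_len(nrow(rec$data)))
    data[c, ] <- signal::filtfilt(ma, rec$data[c, ])[keep]
  markers <- rec$markers
  markers$sample_index <- as.integer(round(markers$sample_index / k))
  continuous_recording(rec$modality, target_fs, data, rec$channel_labels,
                       rec$units, markers)
}

#' Epoch set
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param time time axis in seconds relative to task onset (includes 0).
#' @param labels trial labels.
#' @param session_ids per-trial session identifiers.
#' @param modality `"EEG"`, `"HbO"` or `"HbR"`.
#' @param channel_labels channel names.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time, labels, session_ids, modality,
                      channel_labels) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels),
            dim(data)[3] == length(time))
  structure(list(data = data, fs = fs, time = time,
                 labels = as.character(labels),
                 session_ids = as.integer(session_ids), modality = modality,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %g Hz (%s)\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset an epoch set by trial index
#' @param x an [epoch_set()].
#' @param idx trial indices.
#' @return the subset `epoch_set`.
#' @export
subset_epochs <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$fs, x$time, x$labels[idx],
            x$session_ids[idx], x$modality, x$channel_labels)
}

#' Concatenate epoch sets along trials
#' @param sets list of compatible [epoch_set()]s.
#' @return one combined `epoch_set`.
#' @export
combine_epochs <- function(sets) {
  stopifnot(length(sets) >= 1)
  n <- sum(vapply(sets, function(s) dim(s$data)[1], 1L))
  d <- dim(sets[[1]]$data)
  data <- array(0, c(n, d[2], d[3]))
  labels <- character(n); sess <- integer(n)
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    data[at + seq_len(k), , ] <- s$data
    labels[at + seq_len(k)] <- s$labels
    sess[at + seq_len(k)] <- s$session_ids
    at <- at + k
  }
  epoch_set(data, sets[[1]]$fs, sets[[1]]$time, labels, sess,
            sets[[1]]$modality, sets[[1]]$channel_labels)
}

#' Cut a continuous recording into trial epochs
#'
#' Epochs span the closed window (default -5 to 5 s) around each task-onset
#' marker on a sample grid that contains t = 0 exactly; the sample count is
#' `round(span * fs) + 1` (1001 at 100 Hz, 126 at 12.5 Hz).
#'
#' @param rec a [continuous_recording()] with task-onset markers.
#' @param schedule optional [make_schedule()] result; supplies the session id
#'   and is cross-checked against the markers.
#' @param window epoch window in seconds relative to task onset.
#' @param modality modality tag for the result; derived from the recording
#'   when `NULL`.
#' @return an [epoch_set()].
#' @export
epoch <- function(rec, schedule = NULL, window = c(-5, 5), modality = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$fs
  k0 <- round(window[1] * fs)
  k1 <- k0 + round((window[2] - window[1]) * fs)
  offs <- k0:k1
  n <- ncol(rec$data)
  onsets <- rec$markers$sample_index
  bad <- which(onsets + k0 + 1 < 1 | onsets + k1 + 1 > n)
  if (length(bad))
    stop_hbci(sprintf("epoch window exceeds recording bounds for trial(s) %s",
                      paste(bad, collapse = ", ")), "hbci_truncation_error")
  nt <- length(onsets); nc <- nrow(rec$data)
  data <- array(0, c(nt, nc, length(offs)))
  for (i in seq_len(nt))
    data[i, , ] <- rec$data[, onsets[i] + 1 + offs, drop = FALSE]
  if (!is.null(schedule) &&
      !identical(as.character(schedule$trials$label),
                 as.character(rec$markers$label)))
    stop_hbci("schedule labels do not match recording markers",
              "hbci_alignment_error")
  sess <- if (!is.null(schedule)) rep(schedule$session_id, nt) else rep(0L, nt)
  if (is.null(modality))
    modality <- if (rec$modality == "EEG") "EEG" else "NIRS"
  epoch_set(data, fs, offs / fs, rec$markers$label, sess, modality,
            rec$channel_labels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (default -5 to -2 s, before the instruction appears).
#'
#' @param epochs an [epoch_set()].
#' @param interval baseline interval in seconds.
#' @return the corrected `epoch_set`. Applying it twice is a no-op.
#' @export
baseline_correct <- function(epochs, interval = c(-5, -2)) {
  stopifnot(inherits(epochs, "epoch_set"))
  eps <- 1e-9
  mask <- epochs$time >= interval[1] - eps & epochs$time <= interval[2] + eps
  if (!any(mask))
    stop_hbci("baseline interval contains no samples", "hbci_parameter_error")
  mu <- apply(epochs$data[, , mask, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(mu)  # recycles over the sample dim
  out
}

#' Preprocess a simulated dataset into analysis-ready epochs
#'
#' Runs the standard chain: EEG 1-40 Hz band-pass, optional EOG correction,
#' decimation to `target_fs`; NIRS (after Beer-Lambert inversion when the
#' dataset carries optical density) 0.01-0.2 Hz sixth-order zero-phase
#' Butterworth; both epoched to the window around task onset and
#' baseline-corrected over `baseline`.
#'
#' @param dataset a [simulate_dataset()] result (or a compatible list).
#' @param eog_method EOG correction passed to [remove_eog()].
#' @param eeg_band,eeg_order EEG band-pass settings.
#' @param nirs_band,nirs_order hemodynamic band-pass settings.
#' @param target_fs EEG rate after decimation (default 100).
#' @param window epoch window, seconds.
#' @param baseline baseline interval, seconds.
#' @param optics an [optics_config()] for optical-density input.
#' @return an object of class `bci_trials`: list with `eeg`, `hbo`, `hbr`
#'   [epoch_set()]s pooled over sessions.
#' @export
preprocess_dataset <- function(dataset, eog_method = "regression",
                               eeg_band = c(1, 40), eeg_order = 4,
                               nirs_band = c(0.01, 0.2), nirs_order = 6,
                               target_fs = 100, window = c(-5, 5),
                               baseline = c(-5, -2),
                               optics = optics_config()) {
  eeg_list <- list(); hbo_list <- list(); hbr_list <- list()
  for (s in dataset$sessions) {
    ee <- bandpass(s$eeg, eeg_band[1], eeg_band[2], order = eeg_order,
                   zero_phase = TRUE)
    ee <- remove_eog(ee, s$eog, method = eog_method)
    ee <- decimate(ee, target_fs)
    eeg_list[[length(eeg_list) + 1L]] <-
      baseline_correct(epoch(ee, s$schedule, window), baseline)
    chrom <- if (s$nirs$modality == "NIRS-OD") mbll(s$nirs, optics)
    else split_chromophores(s$nirs)
    for (nm in c("hbo", "hbr")) {
      r <- bandpass(chrom[[nm]], nirs_band[1], nirs_band[2],
                    order = nirs_order, zero_phase = TRUE)
      es <- baseline_correct(epoch(r, s$schedule, window,
                                   modality = toupper(sub("b", "b", nm))),
                             baseline)
      es$modality <- if (nm == "hbo") "HbO" else "HbR"
      if (nm == "hbo") hbo_list[[length(hbo_list) + 1L]] <- es
      else hbr_list[[length(hbr_list) + 1L]] <- es
    }
  }
  structure(list(eeg = combine_epochs(eeg_list),
                 hbo = combine_epochs(hbo_list),
                 hbr = combine_epochs(hbr_list)),
            class = "bci_trials")
}

#' @export
print.bci_trials <- function(x, ...) {
  cat("<bci_trials>\n")
  print(x$eeg); print(x$hbo); print(x$hbr)
  invisible(x)
}
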