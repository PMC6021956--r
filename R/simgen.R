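#' Continuous multimodal recording
#'
#' Lightweight container for one modality's channels-by-samples stream.
#'
#' @param modality one of `"EEG"`, `"EOG"`, `"NIRS-Hb"`, `"NIRS-OD"`.
#' @param fs sampling rate in Hz.
#' @param data numeric matrix, channels x samples.
#' @param channel_labels character vector, one per row of `data`.
#' @param units physical units of `data` (e.g. `"uV"`, `"mol/L"`, `"OD"`).
#' @param markers data.frame with columns `sample_index` (0-based) and
#'   `label`, one row per task onset.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(modality, fs, data, channel_labels, units,
                                 markers = data.frame(sample_index = integer(),
                                                      label = character())) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  assert_scalar_num(fs, "fs", lo = 1e-6)
  dimnames(data) <- NULL
  markers <- data.frame(sample_index = as.integer(markers$sample_index),
                        label = as.character(markers$label))
  rec <- list(modality = modality, fs = fs, data = data,
              channel_labels = as.character(channel_labels), units = units,
              markers = markers)
  class(rec) <- "continuous_recording"
  rec
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %s: %d channels x %d samples @ %g Hz [%s], %d markers\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs, x$units,
              nrow(x$markers)))
  invisible(x)
}

eeg_channels <- function() c("AFp1", "AFp2", "AFF1h", "AFF2h", "AFF5h",
                             "AFF6h", "F3", "F4", "F7", "F8")
nirs_channels <- function() paste0("CH", 1:9)

default_erd <- function() list(
  MA = c(theta = 0.00, alpha = 0.50, beta = 0.30),
  WC = c(theta = 0.20, alpha = 0.45, beta = 0.35),
  BL = c(theta = 0.00, alpha = 0.00, beta = 0.00))

default_ers <- function() list(
  MA = c(theta = 0.40, alpha = 0.00, beta = 0.00),
  WC = c(theta = 0.00, alpha = 0.00, beta = 0.00),
  BL = c(theta = 0.00, alpha = 0.00, beta = 0.00))

# Peak oxygenated-hemoglobin concentration change per class and channel
# (mol/L). MA activates medial prefrontal channels most strongly; WC is
# left-lateralized; baseline evokes nothing.
default_hrf_amp <- function() list(
  MA = 0.85e-6 * c(1.00, 0.95, 0.90, 0.85, 0.80, 0.75, 0.70, 0.65, 0.60),
  WC = 0.80e-6 * c(1.00, 0.55, 0.95, 0.50, 0.90, 0.50, 0.85, 0.45, 0.80),
  BL = rep(0, 9))

# Fixed band-source scalp mixing weights over the 10 frontal channels.
band_mixing <- function() rbind(
  theta = c(1.0, 1.0, 0.9, 0.9, 0.7, 0.7, 0.8, 0.8, 0.5, 0.5),
  alpha = c(0.8, 0.8, 0.9, 0.9, 1.0, 1.0, 0.7, 0.7, 0.6, 0.6),
  beta  = c(0.6, 0.6, 0.8, 0.8, 0.7, 0.7, 1.0, 1.0, 0.9, 0.9))

default_eog_propagation <- function() rbind(
  VEOG = c(0.30, 0.30, 0.25, 0.25, 0.20, 0.20, 0.12, 0.12, 0.05, 0.05),
  HEOG = c(0.10, 0.10, 0.08, 0.08, 0.12, 0.12, 0.05, 0.05, 0.20, 0.20))

#' Simulation configuration
#'
#' Parameters of the synthetic multimodal generator. Defaults emulate the
#' study conditions the pipeline is designed for: three sessions of 30 trials
#' (10 per class among mental arithmetic MA, word chain WC and baseline BL),
#' a 2-s instruction followed by a 5-s task and a 13-15 s rest, class-
#' dependent alpha/beta event-related desynchronization plus theta
#' synchronization on the EEG, and a canonical hemodynamic HbO increase /
#' HbR decrease on the NIRS channels contaminated by Mayer-wave, respiratory
#' and cardiac oscillations. See the package vignette for the rationale
#' behind each default.
#'
#' @param seed integer master seed; identical seed and configuration give
#'   bit-identical datasets.
#' @param n_sessions number of sessions (default 3).
#' @param fs_eeg EEG/EOG sampling rate in Hz (default 200).
#' @param fs_nirs NIRS sampling rate in Hz (default 12.5).
#' @param n_trials_per_class trials per class per session (default 10).
#' @param classes task labels (default MA, WC, BL).
#' @param pre_rest_s,post_rest_s leading/trailing rest in seconds.
#' @param bands named list of EEG band edges in Hz.
#' @param erd_depth per class, per band fractional amplitude reduction of the
#'   band oscillation during the task window (0 = no desynchronization).
#' @param ers_gain per class, per band fractional amplitude gain (event-
#'   related synchronization).
#' @param osc_amp per band oscillation RMS amplitude in microvolts.
#' @param indep_frac amplitude of per-channel independent narrowband activity
#'   relative to the shared band source.
#' @param trial_gain_sd log-normal sd of the per-trial, per-band oscillation
#'   amplitude jitter (models trial-to-trial excitability fluctuations).
#' @param hrf_amp per class, per NIRS channel peak HbO amplitude in mol/L.
#' @param hbr_ratio HbR amplitude as a (positive) fraction of HbO; the HbR
#'   trace is the negative, slightly delayed copy.
#' @param hbr_noise_frac amplitude of the HbR physiological/sensor noise
#'   relative to the HbO noise.
#' @param hbr_delay_s delay of the HbR response relative to HbO, seconds.
#' @param hrf_peak_s,hrf_undershoot_s canonical double-gamma response shape.
#' @param noise named list of noise amplitudes: `eeg_pink`, `eeg_white` (uV
#'   RMS), `mayer`, `respiration`, `cardiac`, `nirs_white`, `nirs_drift`
#'   (mol/L RMS). The Mayer wave sits at 0.1 Hz, respiration at 0.3 Hz,
#'   cardiac at 1.1 Hz, with per-session random phases.
#' @param eog_rate_hz mean blink rate; horizontal saccades occur at half
#'   this rate.
#' @param eog_propagation 2 x 10 matrix of leakage coefficients from the
#'   VEOG/HEOG channels into the frontal EEG channels.
#' @param session_drift_sd log-normal sd of the per-session multiplicative
#'   drift applied to effect amplitudes and channel gains (0 disables drift).
#' @param ramp_s half-cosine ramp length of the task envelope, seconds.
#' @param emit_optical_density if `TRUE`, `simulate_nirs()` applies the
#'   forward Beer-Lambert model and returns dual-wavelength optical density
#'   instead of chromophore concentrations.
#' @param optics an [optics_config()] used for the forward model.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_sessions = 3L, fs_eeg = 200, fs_nirs = 12.5,
                       n_trials_per_class = 10L, classes = c("MA", "WC", "BL"),
                       pre_rest_s = 60, post_rest_s = 60,
                       bands = list(theta = c(4, 8), alpha = c(8, 13),
                                    beta = c(13, 30)),
                       erd_depth = default_erd(), ers_gain = default_ers(),
                       osc_amp = c(theta = 3, alpha = 6, beta = 2.5),
                       indep_frac = 0.4, trial_gain_sd = 0.25,
                       hrf_amp = default_hrf_amp(), hbr_ratio = 0.3,
                       hbr_noise_frac = 0.5, hbr_delay_s = 0.5,
                       hrf_peak_s = 6, hrf_undershoot_s = 16,
                       noise = list(eeg_pink = 6, eeg_white = 1,
                                    mayer = 9e-7, respiration = 4e-7,
                                    cardiac = 1.5e-7, nirs_white = 2.5e-7,
                                    nirs_drift = 9e-7),
                       eog_rate_hz = 0.12,
                       eog_propagation = default_eog_propagation(),
                       session_drift_sd = 0.15, ramp_s = 0.5,
                       emit_optical_density = FALSE,
                       optics = optics_config()) {
  assert_scalar_num(seed, "seed")
  assert_scalar_num(n_sessions, "n_sessions", lo = 1)
  assert_scalar_num(fs_eeg, "fs_eeg", lo = 50)
  assert_scalar_num(fs_nirs, "fs_nirs", lo = 1)
  assert_scalar_num(n_trials_per_class, "n_trials_per_class", lo = 1)
  assert_scalar_num(hbr_ratio, "hbr_ratio", lo = 0, hi = 1)
  for (cl in classes) {
    ed <- erd_depth[[cl]]
    if (is.null(ed) || any(ed < 0) || any(ed > 1))
      stop_hbci(sprintf("erd_depth for class '%s' must lie in [0, 1]", cl),
                "hbci_config_error")
    eg <- ers_gain[[cl]]
    if (is.null(eg) || any(eg < 0))
      stop_hbci(sprintf("ers_gain for class '%s' must be >= 0", cl),
                "hbci_config_error")
    if (is.null(hrf_amp[[cl]]))
      stop_hbci(sprintf("hrf_amp missing for class '%s'", cl),
                "hbci_config_error")
  }
  cfg <- list(seed = as.integer(seed), n_sessions = as.integer(n_sessions),
              fs_eeg = fs_eeg, fs_nirs = fs_nirs,
              n_trials_per_class = as.integer(n_trials_per_class),
              classes = classes, pre_rest_s = pre_rest_s,
              post_rest_s = post_rest_s, bands = bands,
              erd_depth = erd_depth, ers_gain = ers_gain, osc_amp = osc_amp,
              indep_frac = indep_frac, trial_gain_sd = trial_gain_sd,
              hrf_amp = hrf_amp, hbr_ratio = hbr_ratio,
              hbr_noise_frac = hbr_noise_frac,
              hbr_delay_s = hbr_delay_s, hrf_peak_s = hrf_peak_s,
              hrf_undershoot_s = hrf_undershoot_s, noise = noise,
              eog_rate_hz = eog_rate_hz, eog_propagation = eog_propagation,
              session_drift_sd = session_drift_sd, ramp_s = ramp_s,
              emit_optical_density = isTRUE(emit_optical_density),
              optics = optics)
  class(cfg) <- "sim_config"
  cfg
}

session_seed <- function(config, session_id, stream = 0L) {
  as.integer((config$seed * 131L + session_id * 7L + stream) %% .Machine$integer.max)
}

#' Build one session's paradigm schedule
#'
#' Generates a seeded random ordering of `n_trials_per_class` trials per
#' class, each consisting of a 2-s instruction, a 5-s task and a rest drawn
#' uniformly from 13-15 s, preceded and followed by the configured rest
#' periods.
#'
#' @param config a [sim_config()].
#' @param session_id 0-based session index (`< n_sessions`).
#' @return an object of class `paradigm_schedule` with a `trials` data.frame
#'   (`label`, `instruction_onset_s`, `task_onset_s`, `task_len_s`,
#'   `rest_len_s`).
#' @export
make_schedule <- function(config, session_id = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (session_id < 0 || session_id >= config$n_sessions)
    stop_hbci("session_id must lie in [0, n_sessions)", "hbci_config_error")
  n_per <- config$n_trials_per_class
  labels_pool <- rep(config$classes, each = n_per)
  with_seed(session_seed(config, session_id, stream = 0L), {
    labels <- labels_pool[sample.int(length(labels_pool))]
    rest <- stats::runif(length(labels), 13, 15)
  })
  n <- length(labels)
  instr_len <- 2; task_len <- 5
  instruction_onset <- numeric(n)
  cursor <- config$pre_rest_s
  for (i in seq_len(n)) {
    instruction_onset[i] <- cursor
    cursor <- cursor + instr_len + task_len + rest[i]
  }
  sched <- list(session_id = as.integer(session_id),
                pre_rest_s = config$pre_rest_s,
                post_rest_s = config$post_rest_s,
                total_len_s = cursor + config$post_rest_s,
                trials = data.frame(label = labels,
                                    instruction_onset_s = instruction_onset,
                                    task_onset_s = instruction_onset + instr_len,
                                    task_len_s = task_len,
                                    rest_len_s = rest))
  class(sched) <- "paradigm_schedule"
  sched
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("<paradigm_schedule> session %d: %d trials (%s), span %.1f s\n",
              x$session_id, nrow(x$trials),
              paste(sprintf("%s=%d", names(table(x$trials$label)),
                            table(x$trials$label)), collapse = ", "),
              x$total_len_s))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities (peak minus a 1/6-weighted undershoot)
#' normalized so its maximum equals 1. The response is causal:
#' `double_gamma_hrf(0) == 0`.
#'
#' @param t time in seconds (vector, `t >= 0` contributes; negative times
#'   return 0).
#' @param peak_s time-to-peak of the positive lobe, seconds.
#' @param undershoot_s time-to-peak of the undershoot lobe, seconds.
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return unitless amplitude, max 1 over a dense grid.
#' @export
double_gamma_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  shape <- function(tt) {
    h <- stats::dgamma(tt, shape = peak_s + 1, rate = 1) -
      undershoot_ratio * stats::dgamma(tt, shape = undershoot_s + 1, rate = 1)
    h[tt < 0] <- 0
    h
  }
  grid <- seq(0, undershoot_s + 16, by = 0.01)
  peak_val <- max(shape(grid))
  shape(t) / peak_val
}

# 1/f ("pink") noise with unit RMS, via spectral shaping of white noise.
# Computed on a highly composite FFT length and truncated.
pink_noise <- function(n, fs, f_floor = 0.5) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))) * fs / m
  amp <- 1 / sqrt(pmax(f, f_floor))
  amp[1] <- 0
  y <- Re(stats::fft(X * amp, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

# Unit-RMS narrowband noise inside `band` (Hz).
narrowband_noise <- function(n, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  y / stats::sd(y)
}

# Per-sample multiplicative task envelope for one band and a vector of
# trial-specific factors (1 - erd)(1 + ers).
task_envelope <- function(t, schedule, factors, ramp) {
  env <- rep(1, length(t))
  tr <- schedule$trials
  for (i in seq_len(nrow(tr))) {
    f <- factors[i]
    if (f == 1) next
    g <- cosine_gate(t, tr$task_onset_s[i], tr$task_onset_s[i] + tr$task_len_s[i],
                     ramp)
    env <- env * (1 + (f - 1) * g)
  }
  env
}

# Piecewise per-trial gain curve (log-normal), constant from instruction
# onset to the end of the trial's rest, so task/rest power ratios within a
# trial are unaffected.
trial_gain_curve <- function(t, schedule, sd) {
  g <- rep(1, length(t))
  if (sd <= 0) return(g)
  tr <- schedule$trials
  gains <- exp(stats::rnorm(nrow(tr), sd = sd))
  ends <- tr$task_onset_s + tr$task_len_s + tr$rest_len_s
  for (i in seq_len(nrow(tr)))
    g[t >= tr$instruction_onset_s[i] & t < ends[i]] <- gains[i]
  g
}

#' Simulate one session of EEG and EOG
#'
#' Ten frontal EEG channels built from pink background noise plus shared
#' band-limited oscillation sources whose envelope is scaled by
#' `(1 - erd_depth) * (1 + ers_gain)` during task windows, with blink and
#' saccade artifacts generated on two EOG channels and leaked into the EEG
#' through the propagation coefficients.
#'
#' @param schedule a [make_schedule()] result.
#' @param config a [sim_config()].
#' @return list with elements `eeg` and `eog`, both [continuous_recording()]s.
#' @export
simulate_eeg <- function(schedule, config) {
  stopifnot(inherits(schedule, "paradigm_schedule"),
            inherits(config, "sim_config"))
  fs <- config$fs_eeg
  n <- ceiling(schedule$total_len_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  chans <- eeg_channels()
  nch <- length(chans)
  mix <- band_mixing()
  with_seed(session_seed(config, schedule$session_id, stream = 1L), {
    drift <- if (config$session_drift_sd > 0)
      exp(stats::rnorm(1, sd = config$session_drift_sd)) else 1
    ch_gain <- if (config$session_drift_sd > 0)
      exp(stats::rnorm(nch, sd = config$session_drift_sd / 2)) else rep(1, nch)
    eeg <- matrix(0, nch, n)
    for (b in names(config$bands)) {
      band <- config$bands[[b]]
      amp <- config$osc_amp[[b]]
      fac <- vapply(schedule$trials$label, function(cl) {
        erd <- min(config$erd_depth[[cl]][[b]] * drift, 0.98)
        ers <- config$ers_gain[[cl]][[b]] * drift
        (1 - erd) * (1 + ers)
      }, numeric(1))
      env <- task_envelope(t, schedule, fac, config$ramp_s) *
        trial_gain_curve(t, schedule, config$trial_gain_sd)
      shared <- narrowband_noise(n, fs, band) * env
      for (c in seq_len(nch)) {
        indep <- narrowband_noise(n, fs, band) * env
        eeg[c, ] <- eeg[c, ] + amp * (mix[b, c] * shared +
                                        config$indep_frac * indep)
      }
    }
    for (c in seq_len(nch))
      eeg[c, ] <- eeg[c, ] + config$noise$eeg_pink * pink_noise(n, fs) +
        config$noise$eeg_white * stats::rnorm(n)
    eeg <- eeg * ch_gain

    # EOG: blinks on VEOG, saccade steps on HEOG
    eog <- matrix(stats::rnorm(2 * n, sd = 3), 2, n)
    n_blinks <- stats::rpois(1, config$eog_rate_hz * schedule$total_len_s)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, schedule$total_len_s - 0.5))
      w <- max(3L, round(0.3 * fs))
      pulse <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = w))
      for (o in onsets) {
        i0 <- round(o * fs) + 1L
        idx <- i0:min(i0 + w - 1L, n)
        eog[1, idx] <- eog[1, idx] +
          120 * exp(stats::rnorm(1, sd = 0.2)) * pulse[seq_along(idx)]
      }
    }
    n_sacc <- stats::rpois(1, config$eog_rate_hz / 2 * schedule$total_len_s)
    if (n_sacc > 0) {
      onsets <- sort(stats::runif(n_sacc, 0, schedule$total_len_s - 1.2))
      for (o in onsets) {
        len <- round(stats::runif(1, 0.3, 1) * fs)
        i0 <- round(o * fs) + 1L
        idx <- i0:min(i0 + len - 1L, n)
        eog[2, idx] <- eog[2, idx] + sample(c(-80, 80), 1)
      }
    }
    eeg <- eeg + t(config$eog_propagation) %*% eog
  })
  markers <- data.frame(sample_index = round(schedule$trials$task_onset_s * fs),
                        label = schedule$trials$label)
  list(eeg = continuous_recording("EEG", fs, eeg, chans, "uV", markers),
       eog = continuous_recording("EOG", fs, eog, c("VEOG", "HEOG"), "uV",
                                  markers))
}

#' Simulate one session of NIRS chromophore (or optical-density) data
#'
#' Per trial, the HbO trace is the class/channel peak amplitude times the
#' canonical double-gamma response convolved with a 5-s boxcar at the task
#' onset; HbR is a `hbr_ratio`-scaled, slightly delayed negative copy. Mayer
#' (0.1 Hz), respiratory (0.3 Hz) and cardiac (1.1 Hz) sinusoids with random
#' phases, a slow drift and white noise are superimposed. With
#' `emit_optical_density = TRUE` the forward modified Beer-Lambert model is
#' applied to emit dual-wavelength optical density.
#'
#' @inheritParams simulate_eeg
#' @return a [continuous_recording()] with modality `"NIRS-Hb"` (18 channels:
#'   9 HbO then 9 HbR, mol/L) or `"NIRS-OD"` (9 channels x 2 wavelengths).
#' @export
simulate_nirs <- function(schedule, config) {
  stopifnot(inherits(schedule, "paradigm_schedule"),
            inherits(config, "sim_config"))
  fs <- config$fs_nirs
  n <- ceiling(schedule$total_len_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  nch <- 9L
  hrf <- double_gamma_hrf(seq(0, 32, by = 1 / fs), config$hrf_peak_s,
                          config$hrf_undershoot_s)
  # boxcar-convolved response (moving sum of the impulse response over the
  # 5-s task), renormalized to unit peak
  box_len <- round(5 * fs)
  resp <- as.numeric(stats::filter(c(hrf, numeric(box_len)),
                                   rep(1, box_len), sides = 1))
  resp[seq_len(box_len - 1)] <- cumsum(hrf)[seq_len(box_len - 1)]
  resp <- resp / max(resp)
  delay <- round(config$hbr_delay_s * fs)

  with_seed(session_seed(config, schedule$session_id, stream = 2L), {
    drift_fac <- if (config$session_drift_sd > 0)
      exp(stats::rnorm(1, sd = config$session_drift_sd)) else 1
    gains <- exp(stats::rnorm(nrow(schedule$trials), sd = config$trial_gain_sd))
    hbo <- matrix(0, nch, n)
    for (i in seq_len(nrow(schedule$trials))) {
      cl <- schedule$trials$label[i]
      amp <- config$hrf_amp[[cl]] * drift_fac * gains[i]
      if (all(amp == 0)) next
      i0 <- round(schedule$trials$task_onset_s[i] * fs) + 1L
      idx <- i0:min(i0 + length(resp) - 1L, n)
      for (c in seq_len(nch))
        hbo[c, idx] <- hbo[c, idx] + amp[c] * resp[seq_along(idx)]
    }
    hbr <- -config$hbr_ratio *
      cbind(matrix(0, nch, delay), hbo)[, seq_len(n), drop = FALSE]

    # Systemic physiological oscillations are shared across channels (with
    # mild per-channel amplitude scaling); drift and sensor noise are
    # channel-independent. HbR carries the same systemic components at
    # hbr_noise_frac of the HbO amplitude.
    phases <- stats::runif(3, 0, 2 * pi)
    physio_hbo <- config$noise$mayer * sin(2 * pi * 0.1 * t + phases[1]) +
      config$noise$respiration * sin(2 * pi * 0.3 * t + phases[2]) +
      config$noise$cardiac * sin(2 * pi * 1.1 * t + phases[3])
    phases2 <- stats::runif(3, 0, 2 * pi)
    physio_hbr <- config$noise$mayer * sin(2 * pi * 0.1 * t + phases2[1]) +
      config$noise$respiration * sin(2 * pi * 0.3 * t + phases2[2]) +
      config$noise$cardiac * sin(2 * pi * 1.1 * t + phases2[3])
    hnf <- config$hbr_noise_frac
    for (c in seq_len(nch)) {
      g1 <- stats::runif(1, 0.8, 1.2)
      hbo[c, ] <- hbo[c, ] + g1 * physio_hbo +
        config$noise$nirs_drift * narrowband_noise(n, fs, c(0.001, 0.015)) +
        config$noise$nirs_white * stats::rnorm(n)
      g2 <- stats::runif(1, 0.8, 1.2)
      hbr[c, ] <- hbr[c, ] + hnf * (g2 * physio_hbr +
        config$noise$nirs_drift * narrowband_noise(n, fs, c(0.001, 0.015)) +
        config$noise$nirs_white * stats::rnorm(n))
    }
  })
  markers <- data.frame(sample_index = round(schedule$trials$task_onset_s * fs),
                        label = schedule$trials$label)
  labels <- c(paste0(nirs_channels(), ".HbO"), paste0(nirs_channels(), ".HbR"))
  rec <- continuous_recording("NIRS-Hb", fs, rbind(hbo, hbr), labels, "mol/L",
                              markers)
  if (config$emit_optical_density)
    rec <- forward_mbll(rec, config$optics)
  rec
}

#' Split a combined chromophore recording into HbO and HbR recordings
#'
#' @param rec a `"NIRS-Hb"` [continuous_recording()] whose channel labels end
#'   in `.HbO` / `.HbR`.
#' @return list with elements `hbo` and `hbr`.
#' @export
split_chromophores <- function(rec) {
  stopifnot(rec$modality == "NIRS-Hb")
  is_hbo <- grepl("\\.HbO$", rec$channel_labels)
  list(hbo = continuous_recording("NIRS-Hb", rec$fs,
                                  rec$data[is_hbo, , drop = FALSE],
                                  sub("\\.HbO$", "", rec$channel_labels[is_hbo]),
                                  rec$units, rec$markers),
       hbr = continuous_recording("NIRS-Hb", rec$fs,
                                  rec$data[!is_hbo, , drop = FALSE],
                                  sub("\\.HbR$", "", rec$channel_labels[!is_hbo]),
                                  rec$units, rec$markers))
}

#' Simulate a complete multi-session dataset
#'
#' @param config a [sim_config()].
#' @return an object of class `bci_dataset`: a list with `config` and
#'   `sessions`, each session holding `schedule`, `eeg`, `eog` and `nirs`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sessions <- lapply(seq_len(config$n_sessions) - 1L, function(s) {
    sched <- make_schedule(config, s)
    ee <- simulate_eeg(sched, config)
    list(schedule = sched, eeg = ee$eeg, eog = ee$eog,
         nirs = simulate_nirs(sched, config))
  })
  structure(list(config = config, sessions = sessions), class = "bci_dataset")
}

#' @export
print.bci_dataset <- function(x, ...) {
  n_tr <- sum(vapply(x$sessions, function(s) nrow(s$schedule$trials), 1L))
  cat(sprintf("<bci_dataset> %d sessions, %d trials, EEG @ %g Hz, NIRS @ %g Hz\n",
              length(x$sessions), n_tr, x$config$fs_eeg, x$config$fs_nirs))
  invisible(x)
}
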