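# Synthetic paradigm schedules and multimodal recordings.

test_that("schedules have the paradigm structure: 10 per class, 2 s instruction, 13-15 s rest", {
  cfg <- sim_config(seed = 11)
  sch <- make_schedule(cfg, 0)
  expect_equal(nrow(sch$trials), 30)
  expect_true(all(table(sch$trials$label) == 10))
  expect_equal(sch$trials$task_onset_s - sch$trials$instruction_onset_s,
               rep(2, 30))
  expect_true(all(sch$trials$task_len_s == 5))
  expect_true(all(sch$trials$rest_len_s >= 13 & sch$trials$rest_len_s <= 15))
  # strictly increasing, non-overlapping
  ends <- sch$trials$task_onset_s + sch$trials$task_len_s +
    sch$trials$rest_len_s
  expect_true(all(diff(sch$trials$instruction_onset_s) > 0))
  expect_true(all(sch$trials$instruction_onset_s[-1] >= ends[-30] - 1e-9))
  # total span bounded by the rest-length extremes
  lo <- cfg$pre_rest_s + 30 * (2 + 5 + 13) + cfg$post_rest_s
  hi <- cfg$pre_rest_s + 30 * (2 + 5 + 15) + cfg$post_rest_s
  expect_gte(sch$total_len_s, lo)
  expect_lte(sch$total_len_s, hi)
  # and equals the sum of its parts
  expect_equal(sch$total_len_s,
               cfg$pre_rest_s + sum(2 + 5 + sch$trials$rest_len_s) +
                 cfg$post_rest_s)
})

test_that("schedule generation is deterministic and validated", {
  cfg <- sim_config(seed = 5)
  expect_identical(make_schedule(cfg, 1), make_schedule(cfg, 1))
  expect_error(make_schedule(cfg, 3), class = "hbci_config_error")
  expect_error(sim_config(erd_depth = list(MA = c(theta = 0, alpha = 2, beta = 0),
                                           WC = c(theta = 0, alpha = 0, beta = 0),
                                           BL = c(theta = 0, alpha = 0, beta = 0))),
               class = "hbci_config_error")
})

test_that("double-gamma response is causal, unit-peak, and peaks at peak_s", {
  expect_equal(double_gamma_hrf(0), 0)
  grid <- seq(0, 30, by = 0.01)
  h <- double_gamma_hrf(grid)
  expect_equal(max(h), 1, tolerance = 1e-12)
  expect_lt(abs(grid[which.max(h)] - 6), 0.011 + 0.005)
  # monotone rise before the peak
  h2 <- double_gamma_hrf(2)
  expect_gt(h2, 0); expect_lt(h2, 1)
  expect_lt(h2, double_gamma_hrf(6))
  # small undershoot after the peak
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.25)
})

test_that("alpha ERD scales task-window band variance by (1 - depth)^2", {
  # isolate the oscillation: almost no background, no gain jitter or drift
  cfg <- sim_config(seed = 21, n_sessions = 3, n_trials_per_class = 10,
                    classes = c("MA", "BL"), fs_eeg = 100,
                    pre_rest_s = 8, post_rest_s = 8,
                    erd_depth = list(MA = c(theta = 0, alpha = 0.5, beta = 0),
                                     BL = c(theta = 0, alpha = 0, beta = 0)),
                    ers_gain = list(MA = c(theta = 0, alpha = 0, beta = 0),
                                    BL = c(theta = 0, alpha = 0, beta = 0)),
                    trial_gain_sd = 0, session_drift_sd = 0,
                    osc_amp = c(theta = 0.01, alpha = 6, beta = 0.01),
                    noise = list(eeg_pink = 0.2, eeg_white = 0.1,
                                 mayer = 0, respiration = 0, cardiac = 0,
                                 nirs_white = 1e-9, nirs_drift = 0),
                    eog_propagation = matrix(0, 2, 10))
  eps <- list()
  for (s in 0:2) {
    sch <- make_schedule(cfg, s)
    rec <- simulate_eeg(sch, cfg)$eeg
    eps[[s + 1]] <- epoch(rec, sch)
  }
  ep <- combine_epochs(eps)
  alpha <- filter_bank(ep, feature_spec())$alpha
  task <- alpha$time >= 1 & alpha$time <= 4.5   # inside the ramped plateau
  rest <- alpha$time >= -4.5 & alpha$time <= -1
  ratio_for <- function(cl) {
    idx <- which(alpha$labels == cl)
    v_task <- mean(apply(alpha$data[idx, , task], c(1, 2), stats::var))
    v_rest <- mean(apply(alpha$data[idx, , rest], c(1, 2), stats::var))
    v_task / v_rest
  }
  expect_equal(ratio_for("MA"), 0.25, tolerance = 0.2)
  expect_equal(ratio_for("BL"), 1, tolerance = 0.15)
})

test_that("zero EOG propagation leaves EEG untouched by ocular events", {
  base <- list(seed = 31, n_sessions = 1, n_trials_per_class = 3,
               fs_eeg = 100, pre_rest_s = 8, post_rest_s = 8,
               eog_propagation = matrix(0, 2, 10))
  cfg1 <- do.call(sim_config, c(base, list(eog_rate_hz = 0.01)))
  cfg2 <- do.call(sim_config, c(base, list(eog_rate_hz = 2)))
  sch <- make_schedule(cfg1, 0)
  e1 <- simulate_eeg(sch, cfg1)
  e2 <- simulate_eeg(sch, cfg2)
  expect_identical(e1$eeg$data, e2$eeg$data)
  expect_false(identical(e1$eog$data, e2$eog$data))
})

test_that("noiseless hemodynamics: HbO rises and HbR falls over 2-5 s after onset", {
  cfg <- sim_config(seed = 41, n_sessions = 1, n_trials_per_class = 2,
                    classes = c("MA", "BL"), pre_rest_s = 10, post_rest_s = 20,
                    trial_gain_sd = 0, session_drift_sd = 0,
                    erd_depth = list(MA = c(theta = 0, alpha = 0, beta = 0),
                                     BL = c(theta = 0, alpha = 0, beta = 0)),
                    ers_gain = list(MA = c(theta = 0, alpha = 0, beta = 0),
                                    BL = c(theta = 0, alpha = 0, beta = 0)),
                    noise = list(eeg_pink = 1, eeg_white = 1, mayer = 0,
                                 respiration = 0, cardiac = 0,
                                 nirs_white = 0, nirs_drift = 0))
  sch <- make_schedule(cfg, 0)
  rec <- simulate_nirs(sch, cfg)
  chrom <- split_chromophores(rec)
  hbo <- baseline_correct(epoch(chrom$hbo, sch, modality = "HbO"))
  hbr <- baseline_correct(epoch(chrom$hbr, sch, modality = "HbR"))
  late <- hbo$time >= 2 & hbo$time <= 5
  ma <- which(hbo$labels == "MA")
  expect_true(all(apply(hbo$data[ma, , late], c(1, 2), mean) > 0))
  expect_true(all(apply(hbr$data[ma, , late], c(1, 2), mean) < 0))
  # null amplitude: zero everywhere in a noiseless world
  cfg0 <- sim_config(seed = 41, n_sessions = 1, n_trials_per_class = 2,
                     classes = c("MA", "BL"), pre_rest_s = 10, post_rest_s = 20,
                     trial_gain_sd = 0, session_drift_sd = 0,
                     hrf_amp = list(MA = rep(0, 9), BL = rep(0, 9)),
                     noise = list(eeg_pink = 1, eeg_white = 1, mayer = 0,
                                  respiration = 0, cardiac = 0,
                                  nirs_white = 0, nirs_drift = 0))
  rec0 <- simulate_nirs(make_schedule(cfg0, 0), cfg0)
  expect_equal(max(abs(rec0$data)), 0)
})

test_that("forward optical density inverts back through the Beer-Lambert law", {
  cfg <- sim_config(seed = 43, n_sessions = 1, n_trials_per_class = 2,
                    classes = c("MA", "BL"), pre_rest_s = 10, post_rest_s = 20,
                    trial_gain_sd = 0, session_drift_sd = 0,
                    noise = list(eeg_pink = 1, eeg_white = 1, mayer = 0,
                                 respiration = 0, cardiac = 0,
                                 nirs_white = 0, nirs_drift = 0))
  sch <- make_schedule(cfg, 0)
  rec <- simulate_nirs(sch, cfg)
  chrom <- split_chromophores(rec)
  od <- forward_mbll(rec, cfg$optics)
  expect_identical(od$modality, "NIRS-OD")
  back <- mbll(od, cfg$optics)
  scale <- max(abs(chrom$hbo$data))
  expect_lt(max(abs(back$hbo$data - chrom$hbo$data)) / scale, 1e-10)
  expect_lt(max(abs(back$hbr$data - chrom$hbr$data)) / scale, 1e-10)
})

test_that("datasets are deterministic, class-balanced and seed-sensitive", {
  cfg <- tiny_config(seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sessions, d2$sessions)
  expect_length(d1$sessions, 2)
  expect_equal(nrow(d1$sessions[[1]]$eeg$markers), 9)
  d3 <- simulate_dataset(tiny_config(seed = 10))
  expect_false(identical(d1$sessions[[1]]$eeg$data, d3$sessions[[1]]$eeg$data))
  for (d in list(d1, d3))
    expect_true(all(table(d$sessions[[1]]$schedule$trials$label) == 3))
  # default scale: 3 sessions x 30 trials
  full <- sim_config(seed = 1)
  expect_equal(full$n_sessions * full$n_trials_per_class * 3, 90)
})

test_that("markers map onto schedule onsets and recordings cover the session", {
  cfg <- tiny_config(seed = 13)
  ds <- simulate_dataset(cfg)
  s <- ds$sessions[[1]]
  expect_equal(s$eeg$markers$sample_index,
               round(s$schedule$trials$task_onset_s * cfg$fs_eeg))
  expect_equal(as.character(s$eeg$markers$label), s$schedule$trials$label)
  expect_gte(ncol(s$eeg$data), s$schedule$total_len_s * cfg$fs_eeg)
  expect_gte(ncol(s$nirs$data), s$schedule$total_len_s * cfg$fs_nirs)
})

test_that("stronger effects give higher decodability (monotonicity over seeds)", {
  scale_cfg <- function(seed, erd_scale, hrf_scale) {
    ed <- lapply(list(MA = c(theta = 0, alpha = 0.5, beta = 0.3),
                      BL = c(theta = 0, alpha = 0, beta = 0)),
                 function(v) v * erd_scale)
    sim_config(seed = seed, n_sessions = 1, n_trials_per_class = 10,
               classes = c("MA", "BL"), fs_eeg = 100, pre_rest_s = 8,
               post_rest_s = 8, erd_depth = ed,
               ers_gain = list(MA = c(theta = 0.4 * erd_scale, alpha = 0, beta = 0),
                               BL = c(theta = 0, alpha = 0, beta = 0)),
               hrf_amp = list(MA = hrf_scale * hbci:::default_hrf_amp()$MA,
                              BL = rep(0, 9)))
  }
  acc <- function(cfg, modality) {
    tr <- make_trials(cfg)
    s <- summary(crossvalidate_offline(tr, c("MA", "BL"), repetitions = 1,
                                       folds = 5, seed = cfg$seed,
                                       modalities = modality))
    s$mean_accuracy
  }
  seeds <- 60:64
  eeg_weak <- mean(sapply(seeds, function(s) acc(scale_cfg(s, 0.15, 1), "EEG")))
  eeg_strong <- mean(sapply(seeds, function(s) acc(scale_cfg(s, 1, 1), "EEG")))
  nirs_weak <- mean(sapply(seeds, function(s) acc(scale_cfg(s, 1, 0.15), "NIRS")))
  nirs_strong <- mean(sapply(seeds, function(s) acc(scale_cfg(s, 1, 1), "NIRS")))
  expect_gte(eeg_strong, eeg_weak)
  expect_gte(nirs_strong, nirs_weak)
})
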