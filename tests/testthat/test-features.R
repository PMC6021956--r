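# Filter-bank CSP log-variance features and windowed hemodynamic statistics.

test_that("filter bank isolates its bands and preserves trial structure", {
  fs <- 100
  time <- seq(-500, 500) / fs
  nt <- 4
  data <- array(0, c(nt, 2, length(time)))
  for (i in seq_len(nt)) for (c in 1:2)
    data[i, c, ] <- sin(2 * pi * 10 * time)
  ep <- epoch_set(data, fs, time, rep(c("MA", "BL"), 2), rep(0L, nt), "EEG",
                  c("a", "b"))
  fb <- filter_bank(ep, feature_spec())
  expect_named(fb, c("theta", "alpha", "beta"))
  for (b in names(fb)) expect_equal(dim(fb[[b]]$data)[1], nt)
  mid <- 300:700
  rms <- function(x) sqrt(mean(x^2))
  gain <- sapply(fb, function(e) rms(e$data[1, 1, mid]) / rms(data[1, 1, mid]))
  expect_gt(gain["alpha"], 0.9)
  expect_lt(20 * log10(gain["theta"]), -20)
  expect_lt(20 * log10(gain["beta"]), -20)
  # empty band list: empty map, no error
  expect_length(filter_bank(ep, feature_spec(eeg_bands = list())), 0)
  expect_error(filter_bank(ep, feature_spec(eeg_bands = list(hf = c(40, 60)))),
               class = "hbci_parameter_error")
})

test_that("CSP on the 2-channel toy problem gives eigenvalues 0.8/0.2 and axis filters", {
  set.seed(10)
  e1 <- epochs_with_cov(diag(c(4, 1)), 6, span = c(0, 5), labels = rep("MA", 6))
  e2 <- epochs_with_cov(diag(c(1, 4)), 6, span = c(0, 5), labels = rep("BL", 6))
  ep <- combine_epochs(list(e1, e2))
  m <- fit_csp(ep, c("MA", "BL"), csp_pairs = 1)
  expect_equal(m$eigenvalues, c(0.8, 0.2), tolerance = 1e-10)
  # filters align with the coordinate axes (up to scale)
  W <- apply(m$W, 2, function(w) abs(w) / max(abs(w)))
  expect_equal(sort(W[, 1]), c(0, 1), tolerance = 1e-8)
  expect_equal(sort(W[, 2]), c(0, 1), tolerance = 1e-8)
})

test_that("CSP jointly diagonalizes and matches a dense generalized-eigen oracle", {
  set.seed(11)
  for (rep_i in 1:5) {
    d <- 10
    C1 <- random_spd(d); C2 <- random_spd(d)
    e1 <- epochs_with_cov(C1, 3, span = c(0, 5), labels = rep("MA", 3))
    e2 <- epochs_with_cov(C2, 3, span = c(0, 5), labels = rep("BL", 3))
    m <- fit_csp(combine_epochs(list(e1, e2)), c("MA", "BL"))
    # trace-normalized class means are what the solver sees
    C1n <- C1 / sum(diag(C1)); C2n <- C2 / sum(diag(C2))
    D1 <- t(m$W) %*% C1n %*% m$W
    D2 <- t(m$W) %*% C2n %*% m$W
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
    expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
    expect_equal(diag(D1) + diag(D2), rep(1, d), tolerance = 1e-8)
    expect_true(all(diff(m$eigenvalues) <= 1e-10))
    expect_true(all(m$eigenvalues >= -1e-10 & m$eigenvalues <= 1 + 1e-10))
    # independent dense solver on the same matrices
    oe <- eigen(solve(C1n + C2n) %*% C1n)
    expect_equal(sort(Re(oe$values)), sort(m$eigenvalues), tolerance = 1e-8)
    for (j in seq_len(d)) {
      v <- Re(oe$vectors[, order(-Re(oe$values))[j]])
      cosang <- abs(sum(v * m$W[, j])) /
        sqrt(sum(v^2) * sum(m$W[, j]^2))
      expect_equal(cosang, 1, tolerance = 1e-8)
    }
  }
})

test_that("CSP eigenvalue symmetry under class order swap", {
  set.seed(12)
  e1 <- epochs_with_cov(random_spd(6), 4, span = c(0, 5), labels = rep("MA", 4))
  e2 <- epochs_with_cov(random_spd(6), 4, span = c(0, 5), labels = rep("BL", 4))
  ep <- combine_epochs(list(e1, e2))
  m12 <- fit_csp(ep, c("MA", "BL"))
  m21 <- fit_csp(ep, c("BL", "MA"))
  expect_equal(m12$eigenvalues, rev(1 - m21$eigenvalues), tolerance = 1e-10)
})

test_that("identical class statistics give eigenvalues 0.5", {
  set.seed(13)
  C <- random_spd(4)
  e1 <- epochs_with_cov(C, 4, span = c(0, 5), labels = rep("MA", 4))
  e2 <- epochs_with_cov(C, 4, span = c(0, 5), labels = rep("BL", 4))
  m <- fit_csp(combine_epochs(list(e1, e2)), c("MA", "BL"), csp_pairs = 2)
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 1e-10)
})

test_that("log-variance features: dimension 18, log-scale shift, unit variance maps to 0", {
  set.seed(14)
  cfg <- tiny_config(seed = 14)
  tr <- make_trials(cfg)
  pair_idx <- which(tr$eeg$labels %in% c("MA", "BL"))
  ep <- subset_epochs(tr$eeg, pair_idx)
  spec <- feature_spec()
  fb <- filter_bank(ep, spec)
  models <- lapply(fb, fit_csp, class_pair = c("MA", "BL"))
  f1 <- csp_features(fb, models, spec)
  expect_equal(ncol(f1$values), 18)
  expect_equal(nrow(f1$values), length(pair_idx))
  # doubling the signal adds log 4 to every feature
  ep2 <- ep; ep2$data <- ep$data * 2
  f2 <- csp_features(filter_bank(ep2, spec), models, spec)
  expect_equal(f2$values, f1$values + log(4), tolerance = 1e-9)
  # a projection with variance exactly 1 gives feature 0
  e_id <- epochs_with_cov(diag(2), 2, span = c(0, 5), labels = c("MA", "BL"))
  m_id <- list(alpha = structure(list(W = diag(2), eigenvalues = c(0.5, 0.5),
                                      selected = 1:2, class_pair = c("MA", "BL"),
                                      channel_labels = c("ch1", "ch2")),
                                 class = "csp_model"))
  fb_id <- list(alpha = e_id)
  f0 <- csp_features(fb_id, m_id, feature_spec(eeg_bands = list(alpha = c(8, 13))))
  expect_equal(max(abs(f0$values)), 0, tolerance = 1e-10)
})

test_that("CSP log-variance features are invariant to invertible channel mixing", {
  set.seed(15)
  d <- 4
  e1 <- epochs_with_cov(random_spd(d), 5, span = c(0, 5), labels = rep("MA", 5))
  e2 <- epochs_with_cov(random_spd(d), 5, span = c(0, 5), labels = rep("BL", 5))
  ep <- combine_epochs(list(e1, e2))
  spec1 <- feature_spec(eeg_bands = list(raw = c(0.1, 24)), csp_pairs = 2)
  extract <- function(e) {
    fb <- list(raw = e)  # skip filtering: the data are already synthetic
    m <- list(raw = fit_csp(e, c("MA", "BL"), csp_pairs = 2))
    csp_features(fb, m, spec1)$values
  }
  # orthogonal mixing preserves per-trial covariance traces, so the
  # trace-normalized CSP solution is exactly congruent
  M <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  epm <- ep
  for (i in seq_len(dim(ep$data)[1]))
    epm$data[i, , ] <- M %*% ep$data[i, , ]
  expect_equal(extract(epm), extract(ep), tolerance = 1e-6)
  # a general invertible mixing changes the class trace ratio and is only
  # approximately invariant; the eigenvalue spectrum stays within a few
  # percent for mild mixings
  M2 <- diag(d) + 0.2 * matrix(stats::rnorm(d * d), d) / sqrt(d)
  ep2 <- ep
  for (i in seq_len(dim(ep$data)[1]))
    ep2$data[i, , ] <- M2 %*% ep$data[i, , ]
  m_a <- fit_csp(ep, c("MA", "BL"), csp_pairs = 2)
  m_b <- fit_csp(ep2, c("MA", "BL"), csp_pairs = 2)
  expect_equal(m_a$eigenvalues, m_b$eigenvalues, tolerance = 0.1)
})

test_that("NIRS features: analytic means and slopes, 54 columns, trial independence", {
  fs <- 12.5
  k <- round(-5 * fs):(round(-5 * fs) + round(10 * fs))
  time <- k / fs
  nch <- 9; nt <- 3
  data <- array(0, c(nt, nch, length(time)))
  data[1, , ] <- 2e-6                                  # constant
  for (c in seq_len(nch)) data[2, c, ] <- 0.001 * time # common ramp
  data[3, , ] <- stats::rnorm(nch * length(time))
  ep <- epoch_set(data, fs, time, c("MA", "WC", "BL"), rep(0L, 3), "HbO",
                  paste0("CH", 1:9))
  nf <- nirs_features(ep, ep, feature_spec())
  expect_equal(ncol(nf$hbo$values), 54)
  expect_equal(ncol(nf$hbr$values), 54)
  means <- nf$hbo$values[1, grepl("mean", colnames(nf$hbo$values))]
  slopes <- nf$hbo$values[1, grepl("slope", colnames(nf$hbo$values))]
  expect_equal(unname(means), rep(2e-6, 27), tolerance = 1e-15)
  expect_equal(unname(slopes), rep(0, 27), tolerance = 1e-15)
  # ramp: slope 0.001 everywhere (window-independent); means follow window
  slopes2 <- nf$hbo$values[2, grepl("slope", colnames(nf$hbo$values))]
  expect_equal(unname(slopes2), rep(0.001, 27), tolerance = 1e-12)
  for (w in 1:3) {
    mask <- hbci:::nirs_window_mask(time, feature_spec()$nirs_windows, w)
    expected_mean <- 0.001 * mean(time[mask])
    got <- nf$hbo$values[2, grepl(sprintf("w%g_%g.mean",
                                          feature_spec()$nirs_windows[[w]][1],
                                          feature_spec()$nirs_windows[[w]][2]),
                                  colnames(nf$hbo$values), fixed = TRUE)]
    expect_equal(unname(got), rep(expected_mean, 9), tolerance = 1e-12)
  }
  # permuting trials permutes rows identically
  perm <- c(3, 1, 2)
  epp <- subset_epochs(ep, perm)
  nfp <- nirs_features(epp, epp, feature_spec())
  expect_equal(nfp$hbo$values, nf$hbo$values[perm, ])
  # endpoint slope variant on the ramp agrees with the least-squares one
  nfe <- nirs_features(ep, ep, feature_spec(slope_method = "endpoint"))
  expect_equal(unname(nfe$hbo$values[2, grepl("slope", colnames(nfe$hbo$values))]),
               rep(0.001, 27), tolerance = 1e-12)
  # windows with < 2 samples are rejected
  expect_error(nirs_features(ep, ep,
                             feature_spec(nirs_windows = list(c(0, 0.05)))),
               class = "hbci_parameter_error")
})
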