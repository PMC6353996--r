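test_that("the reconvolution model has its closed-form limits", {
  n <- 256L
  dt <- 0.05
  delta <- c(1, rep(0, n - 1))
  m <- biexp_model_counts(0.5, 2, a1 = 1000, a2 = 0, background = 0,
                          irf = delta, n_bins = n, bin_width = dt)
  # pure exponential: consecutive-bin ratio is exp(-dt / tau) wherever the
  # model is appreciably above the FFT noise floor
  keep <- which(m > 1e-6 * max(m))
  ratios <- m[keep[-1]] / m[keep[-length(keep)]]
  expect_equal(ratios, rep(exp(-dt / 0.5), length(ratios)), tolerance = 1e-7)
  # homogeneity in the amplitudes
  m2 <- biexp_model_counts(0.5, 2, 2000, 800, 0, delta, n, dt)
  m1 <- biexp_model_counts(0.5, 2, 1000, 400, 0, delta, n, dt)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # total expected counts ~ (a1 tau1 + a2 tau2) / dt for a long window
  m3 <- biexp_model_counts(0.3, 0.9, 500, 300, 0, c(1, rep(0, 4095)),
                           4096L, 0.01)
  expect_equal(sum(m3), (500 * 0.3 + 300 * 0.9) / 0.01, tolerance = 1e-3)
  expect_error(biexp_model_counts(-1, 2, 1, 1, 0, delta, n, dt), "positive")
})

test_that("amplitude-weighted lifetime follows the amplitude formula", {
  f <- list(tau1_ns = 0.2, tau2_ns = 1.0, a1 = 3, a2 = 1)
  expect_equal(amplitude_weighted_tau(f), 0.4)
  expect_equal(amplitude_weighted_tau(list(tau1_ns = 0.3, tau2_ns = 0.9,
                                           a1 = 2, a2 = 2)), 0.6)
  expect_equal(amplitude_weighted_tau(list(tau1_ns = 0.25, tau2_ns = 5,
                                           a1 = 7, a2 = 0)), 0.25)
  expect_error(amplitude_weighted_tau(list(tau1_ns = 1, tau2_ns = 2,
                                           a1 = 0, a2 = 0)), "undefined")
})

test_that("bi-exponential fits recover simulated lifetimes", {
  h <- generate_decay(decay_spec(tau1 = 0.27, tau2 = 0.75, a1 = 1.5, a2 = 1,
                                 irf_fwhm_ns = 0.12, n_photons = 1e6,
                                 seed = 5))
  f <- fit_biexponential(h)
  expect_true(f$converged)
  expect_lt(abs(f$tau1_ns - 0.27) / 0.27, 0.05)
  expect_lt(abs(f$tau2_ns - 0.75) / 0.75, 0.05)
  expect_gt(f$chi2_reduced, 0.8)
  expect_lt(f$chi2_reduced, 1.5)
  # tau ordering and the tau_amp bound
  expect_lt(f$tau1_ns, f$tau2_ns)
  expect_gte(f$tau_amp_ns, f$tau1_ns)
  expect_lte(f$tau_amp_ns, f$tau2_ns)
  # fitted deviance does not exceed the deviance at the truth
  truth_model <- attr(h, "expected")
  dev_truth <- 2 * sum(truth_model - h$counts +
                         ifelse(h$counts > 0,
                                h$counts * log(h$counts / truth_model), 0))
  expect_lte(f$deviance, dev_truth + 1e-6)
})

test_that("a mono-exponential truth is flagged, not over-fitted", {
  h <- generate_decay(decay_spec(tau1 = 0.4, tau2 = 1.0, a1 = 1, a2 = 0,
                                 window_ns = 25, n_photons = 1e6, seed = 2))
  f <- fit_biexponential(h)
  # amplitude-weighted lifetime pins the real component
  expect_lt(abs(f$tau_amp_ns - 0.4) / 0.4, 0.03)
  # either the second component is negligible or the two lifetimes collapse
  expect_true(f$a2 / f$a1 < 0.05 || f$effectively_monoexponential ||
                f$a1 / f$a2 < 0.05)
})

test_that("lifetime recovery holds across the physiological grid", {
  cases <- expand.grid(tau1 = c(0.2, 0.3), tau2 = c(0.7, 1.0),
                       ratio = c(0.5, 2))
  err1 <- err2 <- erramp <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    h <- generate_decay(decay_spec(
      tau1 = cs$tau1, tau2 = cs$tau2, a1 = cs$ratio, a2 = 1,
      n_bins = 2048L, n_photons = 1e6, seed = 100 + i
    ))
    f <- fit_biexponential(h)
    err1[i] <- abs(f$tau1_ns - cs$tau1) / cs$tau1
    err2[i] <- abs(f$tau2_ns - cs$tau2) / cs$tau2
    truth_amp <- (cs$ratio * cs$tau1 + cs$tau2) / (cs$ratio + 1)
    erramp[i] <- abs(f$tau_amp_ns - truth_amp) / truth_amp
  }
  expect_lt(median(err1), 0.05)
  expect_lt(median(err2), 0.05)
  expect_lt(median(erramp), 0.03)
})

test_that("halving the bin width leaves lifetime estimates unchanged", {
  base <- decay_spec(tau1 = 0.3, tau2 = 0.9, n_bins = 1024L,
                     n_photons = 1e6, seed = 8)
  fine <- decay_spec(tau1 = 0.3, tau2 = 0.9, n_bins = 2048L,
                     n_photons = 1e6, seed = 8)
  f1 <- fit_biexponential(generate_decay(base))
  f2 <- fit_biexponential(generate_decay(fine))
  expect_lt(abs(f1$tau1_ns - f2$tau1_ns) / f2$tau1_ns, 0.01 + 2e-2)
  expect_lt(abs(f1$tau2_ns - f2$tau2_ns) / f2$tau2_ns, 0.01 + 2e-2)
})

test_that("reduced chi-squared is calibrated on well-specified simulations", {
  ch <- vapply(1:8, function(s) {
    h <- generate_decay(decay_spec(tau1 = 0.3, tau2 = 0.9,
                                   n_bins = 2048L, seed = s))
    fit_biexponential(h)$chi2_reduced
  }, numeric(1))
  expect_gt(mean(ch), 0.9)
  expect_lt(mean(ch), 1.1)
})

test_that("per-cell fitting is deterministic and renders within range", {
  h <- generate_decay(fast_decay_spec(tau1 = 0.3, tau2 = 0.9, seed = 3,
                                      n_photons = 5e5))
  fits <- fit_cell_decays(list("1" = h, "2" = h))
  expect_equal(fits$tau1_ns[1], fits$tau1_ns[2])
  expect_equal(fits$tau_amp_ns[1], fits$tau_amp_ns[2])
  # rendering endpoints: clamp below 0.2 ns and above 1.0 ns
  lab <- segmentation_labels(matrix(c(1L, 2L, 0L), 1),
                             matrix(0L, 1, 3))
  fits2 <- data.frame(cell_id = c("1", "2"),
                      tau_amp_ns = c(0.05, 3.0))
  img <- render_flim(lab, fits2)
  lut <- grDevices::col2rgb(grDevices::colorRampPalette(
    c("#0000C0", "#00A0E0", "#00C040", "#E0E000", "#E00000")
  )(256)) / 255
  expect_equal(img[1, 1, ], unname(lut[, 1]))   # blue end
  expect_equal(img[1, 2, ], unname(lut[, 256])) # red end
  expect_equal(img[1, 3, ], c(0, 0, 0))         # background black
})

test_that("fits fail loudly on starved histograms", {
  h <- decay_histogram(rep(1, 128), 0.1, irf = c(1, rep(0, 127)))
  expect_error(fit_biexponential(h), "total counts")
})
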