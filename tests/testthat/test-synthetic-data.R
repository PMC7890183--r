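# Generators: seed determinism, ground-truth recovery, validation.

test_that("every generator is deterministic in its seed", {
  spec <- coupling_spec(list(c(1, 2)), band = c(8, 13))
  r1 <- gen_coupled_eeg(spec, n_channels = 3, fs = 200, duration_s = 4, seed = 7)
  r2 <- gen_coupled_eeg(spec, n_channels = 3, fs = 200, duration_s = 4, seed = 7)
  expect_identical(r1$data, r2$data)
  expect_false(identical(
    r1$data,
    gen_coupled_eeg(spec, n_channels = 3, fs = 200, duration_s = 4, seed = 8)$data))

  s1 <- gen_eog_artifacts(r1, propagation = c(0.5, 0.2, 0), seed = 3)
  s2 <- gen_eog_artifacts(r1, propagation = c(0.5, 0.2, 0), seed = 3)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$veog_true, s2$veog_true)

  cs <- cop_spec(duration_s = 20, fs = 50)
  expect_identical(gen_cop(cs, seed = 11)$ap, gen_cop(cs, seed = 11)$ap)

  expect_identical(gen_null_pvalues(4, 10, seed = 2),
                   gen_null_pvalues(4, 10, seed = 2))
})

test_that("generators do not clobber the session RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(gen_null_pvalues(2, 2, seed = 99))
  expect_identical(rnorm(1), a)
})

test_that("perfectly coupled pair at +90 degrees gives wPLI 1 downstream", {
  spec <- coupling_spec(list(c(1, 2)), band = c(8, 13), phase_lag = pi / 2,
                        coupling_strength = 1, snr_db = Inf)
  rec <- gen_coupled_eeg(spec, n_channels = 2, fs = 250, duration_s = 6, seed = 1)
  expect_equal(wpli(rec$data[1, ], rec$data[2, ]), 1, tolerance = 1e-12)
})

test_that("uncoupled and zero-lag-mixed pairs are suppressed by wPLI on long recordings", {
  vals0 <- vapply(1:12, function(sd) {
    r <- gen_coupled_eeg(coupling_spec(list(c(1, 2)), band = c(8, 13),
                                       coupling_strength = 0),
                         n_channels = 2, fs = 200, duration_s = 40, seed = sd)
    wpli(r$data[1, ], r$data[2, ])
  }, numeric(1))
  expect_lt(mean(vals0), 0.1)

  mix <- diag(2)
  mix[2, 1] <- 1  # channel 2 shares source 1 instantaneously
  res <- vapply(1:12, function(sd) {
    r <- gen_coupled_eeg(coupling_spec(list(), band = c(8, 13)),
                         mixing = mixing_model(mix),
                         n_channels = 2, fs = 200, duration_s = 40, seed = sd)
    c(wpli(r$data[1, ], r$data[2, ]), cor(r$data[1, ], r$data[2, ]))
  }, numeric(2))
  expect_lt(mean(res[1, ]), 0.1)        # phase index suppressed
  expect_gt(mean(res[2, ]), 0.5)        # amplitude correlation survives
})

test_that("downstream wPLI is monotone in coupling strength", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mw <- vapply(grid, function(s) {
    mean(vapply(1:6, function(sd) {
      r <- gen_coupled_eeg(coupling_spec(list(c(1, 2)), band = c(8, 13),
                                         coupling_strength = s),
                           n_channels = 2, fs = 200, duration_s = 10, seed = sd)
      wpli(r$data[1, ], r$data[2, ])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid, mw, method = "spearman"), 0.9)
})

test_that("coupled-EEG preconditions are enforced", {
  expect_error(coupling_spec(list(c(1, 1))), class = "posturenet_parameter_error")
  expect_error(coupling_spec(list(c(1, 2)), coupling_strength = 1.5),
               class = "posturenet_parameter_error")
  spec <- coupling_spec(list(c(1, 2)), band = c(8, 13))
  expect_error(gen_coupled_eeg(spec, mixing = mixing_model(diag(5)),
                               n_channels = 3, fs = 200, duration_s = 4),
               class = "posturenet_dimension_error")
  expect_error(gen_coupled_eeg(spec, n_channels = 3, fs = 200, duration_s = 0.1),
               class = "posturenet_parameter_error")
})

test_that("ocular contamination has exact known structure", {
  rec <- gen_coupled_eeg(coupling_spec(list(), band = c(8, 13)),
                         n_channels = 3, fs = 200, duration_s = 10, seed = 2)
  zero <- gen_eog_artifacts(rec, propagation = rep(0, 3), seed = 4)
  expect_identical(zero$recording$data, rec$data)

  gains <- c(0.8, 0.4, 0.1)
  sim <- gen_eog_artifacts(rec, blink_rate_hz = 0.5, amplitude_uV = 100,
                           propagation = gains, seed = 4)
  # least squares of the added artifact against the true ocular trace
  for (c in 1:3) {
    added <- sim$recording$data[c, ] - rec$data[c, ]
    b <- sum(added * sim$veog_true) / sum(sim$veog_true^2)
    expect_equal(b, gains[c], tolerance = 1e-8)
  }
  expect_error(gen_eog_artifacts(rec, blink_rate_hz = -1, propagation = gains),
               class = "posturenet_parameter_error")
  expect_error(gen_eog_artifacts(rec, propagation = c(1, 2)),
               class = "posturenet_parameter_error")
})

test_that("generated COP recovers the specified covariance and ellipse area", {
  tr <- gen_cop(cop_spec(duration_s = 600, fs = 50, covariance = diag(2)),
                seed = 5)
  cv <- stats::cov(cbind(tr$ap, tr$ml))
  expect_equal(cv, diag(2), tolerance = 1e-8)
  expect_equal(confidence_ellipse_area(tr$ap, tr$ml),
               pi * stats::qchisq(0.95, 2), tolerance = 0.05)

  sigma <- matrix(c(4, 1, 1, 2), 2, 2)
  tr2 <- gen_cop(cop_spec(duration_s = 120, fs = 50, covariance = sigma), seed = 6)
  expect_equal(stats::cov(cbind(tr2$ap, tr2$ml)), sigma, tolerance = 1e-8)
})

test_that("zero-covariance COP is a constant trace with zero RMS", {
  tr <- gen_cop(cop_spec(duration_s = 20, fs = 50,
                         covariance = matrix(0, 2, 2)), seed = 1)
  expect_equal(rms_sway(tr$ap), 0, tolerance = 1e-12)
  expect_equal(max(abs(tr$ml - tr$ml[1])), 0, tolerance = 1e-10)
})

test_that("COP spectral centroid is recovered across seeds", {
  mfs <- vapply(1:20, function(sd) {
    tr <- gen_cop(cop_spec(duration_s = 600, fs = 50,
                           spectral_centroid_hz = 0.3), seed = sd)
    mean_frequency(tr$ap, tr$fs)
  }, numeric(1))
  expect_lt(abs(mean(mfs) - 0.3), 0.05)
})

test_that("COP spec validation rejects impossible parameters", {
  expect_error(cop_spec(covariance = matrix(c(1, 2, 2, 1), 2, 2)),
               class = "posturenet_parameter_error")  # not PSD
  expect_error(cop_spec(fs = 0.5, spectral_centroid_hz = 0.3),
               class = "posturenet_parameter_error")
  expect_error(cop_spec(regularity = 1), class = "posturenet_parameter_error")
})

test_that("null p-value matrices are uniform i.i.d. draws of the right shape", {
  p <- gen_null_pvalues(3, 2000, seed = 42)
  expect_equal(dim(p), c(2000L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(stats::ks.test(as.numeric(p), "punif")$p.value, 0.01)
  expect_error(gen_null_pvalues(0, 10), class = "posturenet_parameter_error")
})
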