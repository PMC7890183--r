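# Preprocessing chain: broadband FIR response, EOG derivation and
# regression, epoching arithmetic, amplitude rejection, sub-band filters.

make_rec <- function(data, fs = 500, eog = NULL) {
  eeg_recording(data, fs, eog = eog)
}

test_that("broadband FIR removes DC and passes mid-band with flat gain", {
  fs <- 500
  n <- 10 * fs
  tt <- seq_len(n) / fs
  dc <- make_rec(matrix(100, 1, n), fs)
  fdc <- broadband_filter(dc)
  expect_lt(max(abs(fdc$data[1, (2 * fs):(8 * fs)])), 0.1)

  mid <- make_rec(matrix(sin(2 * pi * 10 * tt), 1, n), fs)
  fmid <- broadband_filter(mid)
  expect_equal(max(abs(fmid$data[1, (2 * fs):(8 * fs)])), 1, tolerance = 0.02)

  hi <- make_rec(matrix(sin(2 * pi * 80 * tt), 1, n), fs)
  fhi <- broadband_filter(hi)
  atten <- 20 * log10(max(abs(fhi$data[1, (2 * fs):(8 * fs)])))
  expect_lt(atten, -60)

  expect_error(broadband_filter(make_rec(matrix(0, 1, 100), fs = 100)),
               class = "posturenet_parameter_error")
})

test_that("bipolar EOG derivation subtracts the correct electrodes", {
  n <- 1000
  same <- matrix(rnorm(n), 1, n)[rep(1, 4), ]
  rownames(same) <- c("supra", "infra", "left", "right")
  rec <- make_rec(matrix(0, 2, n), eog = same)
  d <- derive_eog(rec)
  expect_equal(max(abs(d$veog)), 0)
  expect_equal(max(abs(d$heog)), 0)

  tmpl <- numeric(n)
  tmpl[100:199] <- 50 * (1 - cos(2 * pi * (0:99) / 99)) / 2
  eog <- rbind(supra = tmpl, infra = 0 * tmpl, left = 0 * tmpl, right = 0 * tmpl)
  d2 <- derive_eog(make_rec(matrix(0, 2, n), eog = eog))
  expect_equal(d2$veog, tmpl)       # upward supraorbital deflection -> positive
  expect_gt(max(d2$veog), 0)

  bad <- eog[c("supra", "left", "right"), , drop = FALSE]
  expect_error(derive_eog(make_rec(matrix(0, 2, n), eog = bad)), "infra")
})

test_that("ocular regression recovers planted gains and spares clean channels", {
  spec <- coupling_spec(list(), band = c(8, 13), snr_db = 10)
  rec <- gen_coupled_eeg(spec, n_channels = 4, fs = 250, duration_s = 20, seed = 3)
  gains <- c(0.8, 0.4, 0.1, 0)
  sim <- gen_eog_artifacts(rec, blink_rate_hz = 0.5, amplitude_uV = 100,
                           propagation = gains, seed = 6)
  f <- broadband_filter(sim$recording)
  eog <- derive_eog(f)
  corr <- regress_out_ocular(f, eog$veog, eog$heog)
  b <- attr(corr, "ocular_coefficients")
  expect_equal(unname(b[, "b_v"]), gains, tolerance = 0.05)
  # artifact-free channel barely distorted
  clean_f <- broadband_filter(sim$clean)
  change <- corr$data[4, ] - clean_f$data[4, ]
  expect_lt(sqrt(mean(change^2)) / sqrt(mean(clean_f$data[4, ]^2)), 0.05)
})

test_that("regression with null EOG is a no-op and collinearity warns", {
  rec <- gen_coupled_eeg(coupling_spec(list(), band = c(8, 13)),
                         n_channels = 2, fs = 200, duration_s = 5, seed = 1)
  z <- rep(0, ncol(rec$data))
  out <- regress_out_ocular(rec, z, z)
  expect_equal(out$data, rec$data, tolerance = 1e-10)

  v <- rnorm(ncol(rec$data))
  expect_warning(regress_out_ocular(rec, v, v + 1e-9 * rnorm(length(v))),
                 "collinear")
})

test_that("epoching uses exact sample-index arithmetic", {
  fs <- 100
  rec <- make_rec(matrix(seq_len(60 * fs), 1, 60 * fs), fs)
  eps <- epoch_recording(rec)
  expect_length(eps$epochs, 29L)           # (60 - 2) / 2
  # epoch k covers samples head + (k-1)*len + 1 .. head + k*len
  expect_equal(unname(eps$epochs[[1]][1, 1]), 2 * fs + 1)
  expect_equal(unname(eps$epochs[[5]][1, 1]), 2 * fs + 4 * 2 * fs + 1)
  expect_equal(unname(eps$epochs[[29]][1, 2 * fs]), 60 * fs)

  short <- make_rec(matrix(rnorm(590), 1, 590), fs)
  expect_length(epoch_recording(short)$epochs, 1L)   # 5.9 s -> one epoch
  expect_error(epoch_recording(make_rec(matrix(0, 1, 300), fs)),
               class = "posturenet_parameter_error")
})

test_that("amplitude rejection drops exactly the contaminated epochs", {
  fs <- 100
  eps <- make_epochs(replicate(6, matrix(0, 2, 2 * fs), simplify = FALSE), fs)
  kept <- reject_artifacts(eps)
  expect_true(all(kept$mask$kept))

  spiky <- eps
  spiky$epochs[[3]][1, 50] <- 150
  r <- reject_artifacts(spiky, amp_threshold_uV = 100)
  expect_equal(which(!r$mask$kept), 3L)
  expect_match(r$mask$reason[3], "amplitude")

  set.seed(2)
  mats <- replicate(10, matrix(rnorm(2 * 2 * fs, sd = 10), 2, 2 * fs),
                    simplify = FALSE)
  hit <- c(2, 5, 9)
  for (k in hit) mats[[k]][2, 10] <- 120
  r2 <- reject_artifacts(make_epochs(mats, fs))
  expect_equal(sum(r2$mask$kept), 10L - length(hit))

  allbad <- make_epochs(list(matrix(200, 1, 50), matrix(-200, 1, 50)), fs)
  expect_error(reject_artifacts(allbad), class = "posturenet_rejection_error")
})

test_that("sub-band filters select their own band", {
  fs <- 250
  n <- 2 * fs
  tt <- seq_len(n) / fs
  tone <- function(f) make_epochs(list(matrix(sin(2 * pi * f * tt), 1, n)), fs)
  gain <- function(eps, band) {
    out <- band_filter(eps, band)
    mid <- (n %/% 4):(3 * n %/% 4)
    max(abs(out$epochs[[1]][1, mid]))
  }
  e10 <- tone(10)
  expect_gt(gain(e10, "alpha"), 0.9)
  expect_lt(20 * log10(gain(e10, "theta")), -20)
  expect_lt(20 * log10(gain(e10, "beta")), -20)
  e6 <- tone(6)
  expect_gt(gain(e6, "theta"), 0.9)
  expect_lt(gain(e6, "alpha"), 0.2)
  expect_lt(gain(e6, "beta"), 0.05)
  expect_error(band_filter(e6, "gamma"), class = "posturenet_parameter_error")
})

test_that("band-filtered white noise concentrates its power in band", {
  fs <- 250
  set.seed(3)
  eps <- make_epochs(list(matrix(rnorm(8 * fs), 1, 8 * fs)), fs)
  out <- band_filter(eps, "alpha")
  psd <- welch_psd(out$epochs[[1]][1, ], fs, window_s = 2)
  inband <- psd$freq >= 7 & psd$freq <= 14   # band edges + transition slack
  expect_gt(sum(psd$power[inband]) / sum(psd$power), 0.8)
})

test_that("band filters are energy-passive", {
  fs <- 200
  set.seed(4)
  for (band in c("theta", "alpha", "beta")) {
    for (k in 1:5) {
      e <- matrix(rnorm(2 * 2 * fs), 2, 2 * fs)
      out <- band_filter(make_epochs(list(e), fs), band)
      expect_lte(stats::var(as.numeric(out$epochs[[1]])),
                 stats::var(as.numeric(e)) * (1 + 1e-8))
    }
  }
})

test_that("the full preprocessing chain runs in the documented order", {
  spec <- coupling_spec(list(c(1, 2)), band = c(8, 13), snr_db = 10)
  rec <- gen_coupled_eeg(spec, n_channels = 4, fs = 250, duration_s = 10, seed = 2)
  sim <- gen_eog_artifacts(rec, blink_rate_hz = 0.3, propagation = rep(0.3, 4),
                           seed = 3)
  eps <- preprocess_eeg(sim$recording)
  expect_s3_class(eps, "epoch_set")
  expect_length(eps$epochs, 4L)            # (10 - 2) / 2
  expect_true(any(eps$mask$kept))
  expect_equal(eps$band, "none")
})
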