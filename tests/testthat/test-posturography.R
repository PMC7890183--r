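# Sway metrics: filter response, RMS, ellipse area, mean frequency,
# sample entropy, task errors.

test_that("COP low-pass keeps slow sway and removes fast components", {
  fs <- 100
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  const <- cop_trial(rep(2.5, length(tt)), rep(-1, length(tt)), fs)
  f <- lowpass_cop(const)
  expect_equal(f$ap, const$ap, tolerance = 1e-8)   # DC gain 1

  slow <- cop_trial(sin(2 * pi * 0.5 * tt), cos(2 * pi * 0.5 * tt), fs)
  fslow <- lowpass_cop(slow)
  mid <- 500:2500
  expect_equal(max(abs(fslow$ap[mid])), 1, tolerance = 0.01)

  fast <- cop_trial(sin(2 * pi * 20 * tt), cos(2 * pi * 20 * tt), fs)
  ffast <- lowpass_cop(fast)
  expect_lt(max(abs(ffast$ap[mid])), 0.01)

  expect_error(lowpass_cop(const, cutoff = 60),
               class = "posturenet_parameter_error")
})

test_that("RMS sway is the dispersion about the mean", {
  expect_equal(rms_sway(rep(5, 100)), 0)
  fs <- 100
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(rms_sway(3 * sin(2 * pi * 2 * tt)), 3 / sqrt(2), tolerance = 1e-3)
  set.seed(1)
  x <- rnorm(10)
  expect_equal(rms_sway(x), sqrt(sum((x - sum(x) / 10)^2) / 10))
  expect_error(rms_sway(numeric(0)), class = "posturenet_parameter_error")
  # offset invariance
  expect_equal(rms_sway(x + 100), rms_sway(x))
})

test_that("confidence ellipse area matches the chi-square formula", {
  s <- sample_with_exact_cov(500, diag(2), seed = 2)
  expect_equal(confidence_ellipse_area(s$x, s$y), pi * qchisq(0.95, 2),
               tolerance = 1e-8)
  s2 <- sample_with_exact_cov(500, matrix(c(4, 0, 0, 1), 2, 2), seed = 3)
  expect_equal(confidence_ellipse_area(s2$x, s2$y), pi * qchisq(0.95, 2) * 2,
               tolerance = 1e-8)
  expect_warning(a0 <- confidence_ellipse_area(rnorm(50), rep(1, 50)),
                 "degenerate")
  expect_equal(a0, 0)
})

test_that("ellipse area is scale-equivariant: CEA(c x) = c^2 CEA(x)", {
  set.seed(4)
  x <- rnorm(200)
  y <- rnorm(200)
  base <- confidence_ellipse_area(x, y)
  for (c in c(0.5, 2, 7)) {
    expect_equal(confidence_ellipse_area(c * x, c * y), c^2 * base,
                 tolerance = 1e-10)
  }
})

test_that("mean frequency is the power-weighted spectral centroid", {
  fs <- 100
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  mf1 <- mean_frequency(sin(2 * pi * 0.3 * tt), fs)
  expect_lt(abs(mf1 - 0.3), 0.02)
  two <- sin(2 * pi * 0.2 * tt) + sin(2 * pi * 0.4 * tt)
  expect_lt(abs(mean_frequency(two, fs) - 0.3), 0.02)
  # offset invariance (DC excluded from the band)
  expect_equal(mean_frequency(two + 50, fs), mean_frequency(two, fs),
               tolerance = 1e-6)
  expect_error(mean_frequency(rep(0, length(tt)), fs),
               class = "posturenet_undefined_error")
})

test_that("mean frequency tracks the direct periodogram centroid of noise", {
  # band-limited noise well inside the resolvable range of a 15 s window
  fs <- 50
  flt <- signal::butter(2, c(0.5, 2) / (fs / 2), "pass")
  for (sd in 1:5) {
    set.seed(sd)
    x <- signal::filtfilt(flt, rnorm(120 * fs))
    mf <- mean_frequency(x, fs)
    ref <- oracle_centroid(x, fs)
    expect_lt(abs(mf - ref) / ref, 0.05)
  }
})

test_that("sample entropy matches the brute-force template count exactly", {
  for (sd in 1:10) {
    set.seed(sd)
    x <- rnorm(50)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, fs = 100, sampen_config(target_fs = 100)),
                 oracle_sampen(x, 2L, r), tolerance = 1e-12)
  }
})

test_that("strictly periodic short-cycle signals have zero sample entropy", {
  x <- rep(c(0, 1), 60)
  expect_equal(sample_entropy(x, fs = 100, sampen_config(target_fs = 100)), 0)
})

test_that("sample entropy is invariant to affine transforms", {
  set.seed(7)
  x <- rnorm(300)
  base <- sample_entropy(x, fs = 100, sampen_config(target_fs = 100))
  expect_equal(sample_entropy(3.2 * x - 40, fs = 100,
                              sampen_config(target_fs = 100)),
               base, tolerance = 1e-10)
})

test_that("sample entropy decimates before matching and validates input", {
  set.seed(8)
  x <- rnorm(2000)
  v <- sample_entropy(x, fs = 1000, sampen_config(target_fs = 100))
  expect_true(is.finite(v) && v > 0)
  expect_error(sample_entropy(x, fs = 100, sampen_config(target_fs = 300)),
               class = "posturenet_parameter_error")
  expect_error(sample_entropy(rep(1, 100), fs = 100,
                              sampen_config(target_fs = 100)),
               class = "posturenet_parameter_error")
  # level-matching templates whose successors always diverge: m-matches
  # exist but no extension matches -> undefined, not a parameter problem
  never_extends <- as.numeric(rbind(0, 1:10))
  expect_error(sample_entropy(never_extends, fs = 100,
                              sampen_config(m = 1L, target_fs = 100)),
               class = "posturenet_undefined_error")
})

test_that("higher generator regularity lowers sample entropy on average", {
  se_at <- function(reg) {
    mean(vapply(1:10, function(sd) {
      tr <- gen_cop(cop_spec(duration_s = 60, fs = 100, regularity = reg),
                    seed = sd)
      sample_entropy(lowpass_cop(tr)$ap, tr$fs)
    }, numeric(1)))
  }
  lo <- se_at(0.2)
  hi <- se_at(0.85)
  expect_lt(hi, lo)
})

test_that("task error keeps the 3-42 s window and does not demean", {
  fs <- 100
  n <- 45 * fs
  target <- sin(2 * pi * 0.2 * seq_len(n) / fs)
  expect_equal(task_error(target, target, fs), 0)
  expect_equal(task_error(target + 2, target, fs), 2, tolerance = 1e-12)
  set.seed(9)
  plate <- target + rnorm(n, sd = 0.3)
  idx <- (3 * fs + 1):(42 * fs)
  expect_equal(task_error(plate, target, fs),
               sqrt(mean((plate[idx] - target[idx])^2)))
  expect_error(task_error(target[1:(30 * fs)], target[1:(30 * fs)], fs),
               class = "posturenet_parameter_error")
})

test_that("standardized errors are percentages of round 1", {
  expect_equal(standardized_errors(rep(2.5, 12)), rep(100, 12))
  e <- c(4, rep(3, 10), 2)
  expect_equal(standardized_errors(e)[12], 50)
  set.seed(10)
  r <- runif(12, 0.5, 3)
  expect_equal(standardized_errors(r), 100 * r / r[1])
  expect_error(standardized_errors(c(0, 1)),
               class = "posturenet_parameter_error")
})

test_that("sway_metrics bundles all seven outcomes per trial", {
  tr <- gen_cop(cop_spec(duration_s = 30, fs = 50), seed = 2)
  m <- sway_metrics(tr, sampen = sampen_config(target_fs = 50))
  expect_named(m, c("rms_ap", "rms_ml", "cea", "mf_ap", "mf_ml",
                    "sampen_ap", "sampen_ml"))
  expect_true(all(unlist(m) >= 0))
})
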