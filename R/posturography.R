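# Behavioral outcome measures from center-of-pressure and
# stabilometer-plate time series: RMS sway amplitude, 95% confidence
# ellipse area, Welch mean frequency, sample entropy, and task errors.

#' Low-pass filter a COP trial
#'
#' 4th-order Butterworth applied forward-backward (zero phase), the
#' conventional conditioning of raw sway trajectories before metric
#' extraction.
#'
#' @param trial a [cop_trial()].
#' @param cutoff cutoff frequency in Hz (default 6).
#' @param order filter order (default 4).
#' @return the filtered [cop_trial()], same length, DC preserved.
#' @export
lowpass_cop <- function(trial, cutoff = 6, order = 4L) {
  stopifnot(inherits(trial, "cop_trial"))
  if (cutoff >= trial$fs / 2)
    abort_param("`cutoff` must lie below the Nyquist frequency")
  out <- trial
  out$ap <- butter_filtfilt(trial$ap, trial$fs, cutoff, "low", order = order)
  out$ml <- butter_filtfilt(trial$ml, trial$fs, cutoff, "low", order = order)
  out
}

#' Root-mean-square sway amplitude
#'
#' RMS of the mean-removed series: sway dispersion about the mean COP
#' position, in the units of the input (cm).
#'
#' @param x numeric series.
#' @return non-negative scalar.
#' @export
rms_sway <- function(x) {
  if (length(x) < 2L) abort_param("series must have at least 2 samples")
  sqrt(mean((x - mean(x))^2))
}

#' 95% confidence ellipse sway area
#'
#' Area of the ellipse covering `coverage` of the AP/ML sway
#' distribution under a bivariate Gaussian model:
#' `pi * chi2(2, coverage) * sqrt(det(S))` with `S` the sample
#' covariance of (AP, ML).
#'
#' @param ap,ml sway series of equal length (cm).
#' @param coverage ellipse coverage probability (default 0.95, giving
#'   the chi-square quantile 5.991).
#' @return area in cm^2; 0 (with a warning) when the sway is degenerate
#'   along an axis.
#' @export
confidence_ellipse_area <- function(ap, ml, coverage = 0.95) {
  if (length(ap) != length(ml)) abort_param("`ap` and `ml` must have equal length")
  if (length(ap) < 3L) abort_param("at least 3 samples required")
  s <- stats::cov(cbind(ap, ml))
  d <- det(s)
  scale <- max(diag(s))
  if (d <= 1e-12 * max(scale^2, .Machine$double.eps)) {
    warning("degenerate sway covariance; ellipse area is 0")
    return(0)
  }
  pi * stats::qchisq(coverage, df = 2) * sqrt(d)
}

#' Mean frequency of a postural signal
#'
#' Power-weighted mean frequency `sum(f * P(f)) / sum(P(f))` of the
#' Welch spectrum (Hann taper, 25%-of-window overlap, segments
#' zero-padded to a 0.02 Hz grid), restricted to `band`; the DC bin is
#' excluded.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_s Welch window length in seconds (default 15).
#' @param overlap_fraction overlap fraction (default 0.25).
#' @param band integration band `(f_min, f_max]` in Hz; default `(0, 6]`.
#' @param resolution_hz frequency-grid spacing (default 0.02 Hz).
#' @return mean frequency in Hz.
#' @export
mean_frequency <- function(x, fs, window_s = 15, overlap_fraction = 0.25,
                           band = c(0, 6), resolution_hz = 0.02) {
  psd <- welch_psd(x, fs, window_s, overlap_fraction, resolution_hz)
  keep <- psd$freq > max(band[1], 0) & psd$freq <= band[2]
  p <- psd$power[keep]
  f <- psd$freq[keep]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= .Machine$double.eps)
    abort_undefined("signal has no power in the analysis band; mean frequency undefined")
  sum(f * p) / tot
}

#' Sample-entropy configuration
#'
#' @param m template length in samples (default 2).
#' @param r_fraction tolerance as a fraction of the series SD (default 0.2).
#' @param target_fs sampling rate the series is decimated to before
#'   matching (default 100 Hz).
#' @return an object of class `sampen_config`.
#' @export
sampen_config <- function(m = 2L, r_fraction = 0.2, target_fs = 100) {
  if (m < 1L) abort_param("`m` must be >= 1")
  if (r_fraction <= 0 || r_fraction >= 1)
    abort_param("`r_fraction` must lie in (0, 1)")
  structure(list(m = as.integer(m), r_fraction = r_fraction,
                 target_fs = target_fs), class = "sampen_config")
}

#' Sample entropy of a sway series
#'
#' `SampEn(m, r, N) = -log(sum(A_i) / sum(B_i))`, where `B_i` counts
#' matches of the i-th template of length `m` and `A_i` of length
#' `m + 1`, under the Chebyshev distance with tolerance
#' `r = r_fraction * SD`, self-matches excluded. The series is decimated
#' (anti-alias filtered) to `cfg$target_fs` first; `r` is taken from the
#' decimated series, so the result is invariant to affine transforms of
#' the signal. Lower values indicate more regular sway.
#'
#' @param x numeric series.
#' @param fs sampling rate of `x`, Hz.
#' @param cfg a [sampen_config()].
#' @return non-negative scalar.
#' @export
sample_entropy <- function(x, fs, cfg = sampen_config()) {
  stopifnot(inherits(cfg, "sampen_config"))
  if (cfg$target_fs > fs) abort_param("`target_fs` must not exceed the source rate")
  if (cfg$target_fs < fs) {
    q <- fs / cfg$target_fs
    if (abs(q - round(q)) > 1e-8)
      abort_param("decimation factor fs / target_fs must be an integer")
    x <- signal::decimate(x, round(q))
  }
  n <- length(x)
  if (n <= cfg$m + 1L) abort_param("decimated series too short for the template length")
  sdx <- stats::sd(x)
  if (sdx == 0) abort_param("series has zero variance; tolerance r undefined")
  r <- cfg$r_fraction * sdx
  counts <- sampen_counts(as.numeric(x), cfg$m, r)
  if (counts[2] == 0)
    abort_undefined("no template matches of length m; sample entropy undefined")
  if (counts[1] == 0)
    abort_undefined("no template matches of length m + 1; sample entropy undefined")
  -log(counts[1] / counts[2])
}

#' Task error of a stabilometer round
#'
#' RMS of the mismatch between plate angle and target over the kept
#' interval. The mismatch is not demeaned: a constant angular offset is
#' an error of the task.
#'
#' @param plate_angle plate angular displacement, degrees.
#' @param target target trace, degrees, same sampling.
#' @param fs sampling rate, Hz.
#' @param keep kept interval in seconds (default 3--42 s, trimming the
#'   unstable head and tail of a 45 s round).
#' @return RMS error in degrees.
#' @export
task_error <- function(plate_angle, target, fs, keep = c(3, 42)) {
  if (length(plate_angle) != length(target))
    abort_param("plate and target series must have equal length")
  if (length(plate_angle) < keep[2] * fs)
    abort_param(sprintf("series must cover %g s", keep[2]))
  idx <- (round(keep[1] * fs) + 1L):round(keep[2] * fs)
  d <- plate_angle[idx] - target[idx]
  sqrt(mean(d^2))
}

#' Standardize practice-round errors to the first round
#'
#' @param per_round_errors vector of per-round RMS errors, degrees;
#'   round 1 first.
#' @return percentages relative to round 1 (round 1 is 100).
#' @export
standardized_errors <- function(per_round_errors) {
  if (length(per_round_errors) < 1L) abort_param("no rounds given")
  if (per_round_errors[1] <= 0)
    abort_param("round-1 error must be positive to standardize")
  100 * per_round_errors / per_round_errors[1]
}

#' All sway metrics of one COP trial
#'
#' Convenience bundle: low-pass conditioning followed by RMS, confidence
#' ellipse area, mean frequency and sample entropy along both axes.
#'
#' @param trial a [cop_trial()].
#' @param lowpass_hz COP conditioning cutoff (default 6 Hz); `NULL` to
#'   skip filtering.
#' @param sampen a [sampen_config()].
#' @param mf_window_s,mf_band Welch settings for the mean frequency.
#' @return one-row data frame with columns `rms_ap`, `rms_ml`, `cea`,
#'   `mf_ap`, `mf_ml`, `sampen_ap`, `sampen_ml`.
#' @export
sway_metrics <- function(trial, lowpass_hz = 6, sampen = sampen_config(),
                         mf_window_s = 15, mf_band = c(0, 6)) {
  stopifnot(inherits(trial, "cop_trial"))
  if (!is.null(lowpass_hz)) trial <- lowpass_cop(trial, cutoff = lowpass_hz)
  data.frame(
    rms_ap = rms_sway(trial$ap),
    rms_ml = rms_sway(trial$ml),
    cea = confidence_ellipse_area(trial$ap, trial$ml),
    mf_ap = mean_frequency(trial$ap, trial$fs, window_s = mf_window_s, band = mf_band),
    mf_ml = mean_frequency(trial$ml, trial$fs, window_s = mf_window_s, band = mf_band),
    sampen_ap = sample_entropy(trial$ap, trial$fs, sampen),
    sampen_ml = sample_entropy(trial$ml, trial$fs, sampen)
  )
}
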