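# Synthetic-data generators: coupled narrowband EEG with controllable
# phase lags, ocular artifacts with known propagation, center-of-pressure
# trajectories with prescribed covariance / spectral centroid /
# regularity, and null p-value matrices. Every downstream stage of the
# pipeline has a recovery test built on these ground truths.

#' Specification of lagged narrowband coupling between channel pairs
#'
#' Describes the ground-truth synchrony structure of a synthetic EEG
#' recording: which channel pairs are coupled, in which frequency band,
#' at what phase lag, and how tightly.
#'
#' @param node_pairs list of length-2 integer vectors `(i, j)`; channel
#'   `j` is generated as a phase-lagged copy of channel `i`.
#' @param band numeric length-2, band edges in Hz.
#' @param phase_lag phase lag in radians imposed on each coupled pair.
#' @param coupling_strength unitless in `[0, 1]`; 1 is a perfect phase
#'   lock, 0 leaves only jittered (effectively independent) phase.
#' @param snr_db sensor signal-to-noise ratio in dB; `Inf` for
#'   noise-free channels.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(node_pairs = list(), band = c(8, 13),
                          phase_lag = pi / 2, coupling_strength = 1,
                          snr_db = Inf) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    abort_param("`band` must be increasing positive edges (Hz)")
  if (coupling_strength < 0 || coupling_strength > 1)
    abort_param("`coupling_strength` must lie in [0, 1]")
  for (p in node_pairs) {
    if (length(p) != 2L || p[1] == p[2] || any(p < 1))
      abort_param("each node pair must be two distinct positive channel indices")
  }
  structure(list(node_pairs = node_pairs, band = as.numeric(band),
                 phase_lag = phase_lag,
                 coupling_strength = coupling_strength, snr_db = snr_db),
            class = "coupling_spec")
}

#' Instantaneous mixing model (volume conduction surrogate)
#'
#' A channels-by-sources gain matrix applied sample-wise, i.e. strictly
#' zero-lag mixing, plus per-channel blink/saccade propagation gains.
#'
#' @param mixing_matrix numeric matrix (channels x sources) or `NULL`
#'   for the identity (each source drives its own channel).
#' @param artifact_propagation per-channel ocular gain vector or `NULL`.
#' @return an object of class `mixing_model`.
#' @export
mixing_model <- function(mixing_matrix = NULL, artifact_propagation = NULL) {
  if (!is.null(mixing_matrix) && any(!is.finite(mixing_matrix)))
    abort_param("mixing matrix must be finite")
  structure(list(mixing_matrix = mixing_matrix,
                 artifact_propagation = artifact_propagation),
            class = "mixing_model")
}

#' Labeled multichannel EEG recording
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel labels (defaults to the 10--20 montage).
#' @param eog optional 4 x samples matrix of periocular channels with
#'   rows `supra`, `infra`, `left`, `right`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, eog = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    if (nrow(data) <= 30L) labels <- montage_1020()[seq_len(nrow(data))]
    else labels <- paste0("Ch", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) abort_param("one label per channel required")
  if (anyDuplicated(labels)) abort_param("channel labels must be unique")
  if (fs <= 0) abort_param("`fs` must be positive")
  if (any(!is.finite(data))) abort_param("EEG data contain non-finite samples")
  if (!is.null(eog)) {
    eog <- as.matrix(eog)
    if (ncol(eog) != ncol(data)) abort_param("EOG and EEG must be time-aligned")
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, eog = eog),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$eog)) "" else ", with EOG"))
  invisible(x)
}

#' Generate coupled narrowband EEG with known phase-lag structure
#'
#' Sources are band-pass-filtered Gaussian noise (4th-order Butterworth
#' at the spec's band edges). A coupled target channel is the
#' analytic-signal phase rotation of its driver, so the instantaneous
#' phase difference equals `phase_lag` plus zero-mean narrowband jitter
#' whose amplitude scales with `1 - coupling_strength`. Channels in no
#' pair carry independent narrowband noise. Optional instantaneous
#' mixing emulates volume conduction; additive white sensor noise is set
#' by `snr_db`.
#'
#' @param spec a [coupling_spec()].
#' @param mixing a [mixing_model()] or `NULL` for identity mixing.
#' @param n_channels number of output channels.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length, seconds; must cover at least two
#'   cycles of the band's low edge.
#' @param seed integer seed; identical seeds give identical recordings.
#' @return an [eeg_recording()].
#' @export
gen_coupled_eeg <- function(spec, mixing = NULL, n_channels = 30L,
                            fs = 1000, duration_s = 10, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (duration_s * fs < 2 * fs / spec$band[1])
    abort_param("recording must cover at least two cycles of the band's low edge")
  if (spec$band[2] >= fs / 2) abort_param("band must lie below the Nyquist frequency")
  for (p in spec$node_pairs) {
    if (any(p > n_channels)) abort_param("node pair index exceeds channel count")
  }
  mix <- if (is.null(mixing) || is.null(mixing$mixing_matrix)) diag(n_channels)
         else mixing$mixing_matrix
  if (nrow(mix) != n_channels)
    abort("mixing matrix rows must equal the channel count",
          class = "posturenet_dimension_error")
  n_src <- ncol(mix)
  n <- round(duration_s * fs)
  with_seed(seed, {
    src <- matrix(stats::rnorm(n_src * n), n_src, n)
    for (k in seq_len(n_src))
      src[k, ] <- butter_filtfilt(src[k, ], fs, spec$band, "pass")
    # unit-variance sources scaled to a plausible cortical amplitude
    src <- 10 * src / apply(src, 1L, stats::sd)
    s <- spec$coupling_strength
    for (p in spec$node_pairs) {
      a <- analytic_signal(src[p[1], ])
      jitter <- butter_filtfilt(stats::rnorm(n), fs, spec$band, "pass")
      jitter <- pi * jitter / stats::sd(jitter)
      src[p[2], ] <- Re(a * exp(-1i * (spec$phase_lag + (1 - s) * jitter)))
    }
    dat <- mix %*% src
    if (is.finite(spec$snr_db)) {
      for (c in seq_len(n_channels)) {
        pw <- mean(dat[c, ]^2)
        if (pw > 0) {
          nsd <- sqrt(pw / 10^(spec$snr_db / 10))
          dat[c, ] <- dat[c, ] + stats::rnorm(n, sd = nsd)
        }
      }
    }
    eeg_recording(dat, fs)
  })
}

# 200 ms raised-cosine blink pulse, unit peak.
blink_template <- function(fs, width_s = 0.2) {
  k <- seq(0, width_s, by = 1 / fs)
  0.5 * (1 - cos(2 * pi * k / width_s))
}

# step-ramp saccade: 50 ms linear rise, 200 ms hold, 50 ms return.
saccade_template <- function(fs, ramp_s = 0.05, hold_s = 0.2) {
  up <- seq(0, 1, length.out = max(2L, round(ramp_s * fs)))
  hold <- rep(1, round(hold_s * fs))
  c(up, hold, rev(up))
}

place_events <- function(n, template, onsets) {
  out <- numeric(n)
  for (t0 in onsets) {
    idx <- t0 + seq_along(template) - 1L
    keep <- idx <= n
    out[idx[keep]] <- out[idx[keep]] + template[keep]
  }
  out
}

#' Contaminate a recording with ocular artifacts of known propagation
#'
#' Adds a blink train (raised-cosine pulses) and horizontal saccades
#' (step-ramps) to the scalp channels through per-channel gain vectors,
#' attaches four periocular channels, and keeps the clean recording so
#' the regression-correction error can be measured against ground truth.
#'
#' @param rec an [eeg_recording()].
#' @param blink_rate_hz mean blink rate (events per second), >= 0.
#' @param amplitude_uV blink peak amplitude at the vertical EOG, microvolts.
#' @param propagation per-channel vertical-EOG gains (length = channels).
#' @param h_propagation per-channel horizontal-EOG gains; default 0.
#' @param saccade_rate_hz mean saccade rate; default 0.2.
#' @param saccade_amplitude_uV saccade amplitude at the horizontal EOG.
#' @param seed integer seed.
#' @return list with elements `recording` (contaminated, EOG channels
#'   attached), `clean` (the input), `veog_true`, `heog_true`,
#'   `propagation`, `h_propagation`.
#' @export
gen_eog_artifacts <- function(rec, blink_rate_hz = 0.3, amplitude_uV = 100,
                              propagation, h_propagation = NULL,
                              saccade_rate_hz = 0.2,
                              saccade_amplitude_uV = 30, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (blink_rate_hz < 0) abort_param("`blink_rate_hz` must be non-negative")
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  if (length(propagation) != nch)
    abort_param("`propagation` must have one gain per channel")
  if (is.null(h_propagation)) h_propagation <- numeric(nch)
  if (length(h_propagation) != nch)
    abort_param("`h_propagation` must have one gain per channel")
  fs <- rec$fs
  with_seed(seed, {
    blink <- amplitude_uV * blink_template(fs)
    sacc <- saccade_amplitude_uV * saccade_template(fs)
    n_blinks <- stats::rpois(1L, blink_rate_hz * n / fs)
    blink_onsets <- sort(sample.int(max(1L, n - length(blink)), n_blinks, replace = TRUE))
    veog_true <- place_events(n, blink, blink_onsets)
    n_sacc <- stats::rpois(1L, saccade_rate_hz * n / fs)
    sacc_onsets <- sort(sample.int(max(1L, n - length(sacc)), n_sacc, replace = TRUE))
    signs <- sample(c(-1, 1), max(n_sacc, 1L), replace = TRUE)
    heog_true <- numeric(n)
    for (k in seq_len(n_sacc)) {
      idx <- sacc_onsets[k] + seq_along(sacc) - 1L
      keep <- idx <= n
      heog_true[idx[keep]] <- heog_true[idx[keep]] + signs[k] * sacc[keep]
    }
    dat <- rec$data + outer(propagation, veog_true) + outer(h_propagation, heog_true)
    # periocular sensors: derivation gains sum to 1 so the bipolar
    # channels reproduce the true ocular sources (plus sensor noise)
    eog <- rbind(supra = 0.8 * veog_true, infra = -0.2 * veog_true,
                 left = -0.5 * heog_true, right = 0.5 * heog_true) +
      matrix(stats::rnorm(4L * n, sd = 1), 4L, n)
    contaminated <- eeg_recording(dat, fs, rec$labels, eog = eog)
    list(recording = contaminated, clean = rec,
         veog_true = veog_true, heog_true = heog_true,
         blink_onsets = blink_onsets, saccade_onsets = sacc_onsets,
         propagation = propagation, h_propagation = h_propagation)
  })
}

#' Specification of a synthetic center-of-pressure trial
#'
#' @param duration_s trial length in seconds.
#' @param fs sampling rate in Hz; must exceed twice the spectral centroid.
#' @param covariance 2x2 symmetric positive semi-definite AP/ML
#'   covariance in cm^2.
#' @param spectral_centroid_hz target centroid of the sway spectrum, Hz.
#' @param regularity in `[0, 1)`: fraction of trajectory variance carried
#'   by a deterministic oscillation at the centroid frequency; higher
#'   values give more self-similar (lower-entropy) sway.
#' @return an object of class `cop_spec`.
#' @export
cop_spec <- function(duration_s = 60, fs = 100, covariance = diag(2),
                     spectral_centroid_hz = 0.3, regularity = 0) {
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    abort_param("`covariance` must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    abort_param("`covariance` must be positive semi-definite")
  if (fs <= 2 * spectral_centroid_hz)
    abort_param("`fs` must exceed twice the spectral centroid")
  if (regularity < 0 || regularity >= 1)
    abort_param("`regularity` must lie in [0, 1)")
  structure(list(duration_s = duration_s, fs = fs, covariance = covariance,
                 spectral_centroid_hz = spectral_centroid_hz,
                 regularity = regularity),
            class = "cop_spec")
}

#' A center-of-pressure trial
#'
#' @param ap,ml anterio-posterior and medio-lateral sway, cm.
#' @param fs sampling rate, Hz.
#' @param trial_id,subject_id,session,group optional metadata.
#' @return an object of class `cop_trial`.
#' @export
cop_trial <- function(ap, ml, fs, trial_id = NA, subject_id = NA,
                      session = NA, group = NA) {
  if (length(ap) != length(ml)) abort_param("`ap` and `ml` must have equal length")
  if (fs <= 0) abort_param("`fs` must be positive")
  if (any(!is.finite(ap)) || any(!is.finite(ml)))
    abort_param("COP samples must be finite")
  structure(list(ap = as.numeric(ap), ml = as.numeric(ml), fs = fs,
                 trial_id = trial_id, subject_id = subject_id,
                 session = session, group = group),
            class = "cop_trial")
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf("<cop_trial> %d samples @ %g Hz (%.1f s)\n",
              length(x$ap), x$fs, length(x$ap) / x$fs))
  invisible(x)
}

#' Generate a synthetic center-of-pressure trajectory
#'
#' Each axis is a realistic broadband sway process: a band-pass filtered
#' white-noise core (order-2 Butterworth, low edge 0.1 Hz since postural
#' corrections bound very slow drift, upper corner solved numerically so
#' the theoretical spectral centroid over the analysis band equals the
#' specification) plus a small high-frequency "tremor" component (up to
#' 3% of variance, 1--6 Hz band-pass), optionally blended with a deterministic
#' oscillation at the centroid frequency (the `regularity` control,
#' which leaves the centroid unchanged and makes the trajectory more
#' self-similar). The two axes are then whitened against their sample
#' covariance and re-colored by the symmetric square root of the target
#' covariance, so the sample covariance of the emitted trial matches the
#' specification exactly.
#'
#' @param spec a [cop_spec()].
#' @param seed integer seed.
#' @param tremor_fraction variance fraction of the 1--6 Hz tremor
#'   component (default 0.03).
#' @param ... metadata passed to [cop_trial()].
#' @return a [cop_trial()].
#' @export
gen_cop <- function(spec, seed = 1L, tremor_fraction = 0.03, ...) {
  stopifnot(inherits(spec, "cop_spec"))
  n <- round(spec$duration_s * spec$fs)
  if (n < 16L) abort_param("trial too short")
  fc <- spec$spectral_centroid_hz
  fs <- spec$fs
  hf_band <- c(1, min(6, 0.4 * fs))
  if (fs <= 2.5 * hf_band[1])
    abort_param("`fs` too low for the tremor band of the sway model")
  hf_flt <- signal::butter(4L, hf_band / (fs / 2), "pass")
  c_hf <- filter_band_centroid(hf_flt, fs)
  w_hf <- min(tremor_fraction, 0.3 * fc / c_hf)
  target_core <- (fc - w_hf * c_hf) / (1 - w_hf)
  core_lo <- 0.1
  core_cent <- function(f_hi) {
    filter_band_centroid(signal::butter(2L, c(core_lo, f_hi) / (fs / 2), "pass"), fs)
  }
  if (core_cent(core_lo + 0.02) > target_core)
    abort_param("spectral centroid too low for the sway model (minimum ~0.15 Hz)")
  f_hi <- stats::uniroot(function(f) core_cent(f) - target_core,
                         c(core_lo + 0.02, 0.45 * fs), tol = 1e-4)$root
  with_seed(seed, {
    z <- matrix(0, 2L, n)
    for (k in 1:2) {
      core <- butter_filtfilt(stats::rnorm(n), fs, c(core_lo, f_hi), "pass",
                              order = 2L)
      hf <- butter_filtfilt(stats::rnorm(n), fs, hf_band, "pass")
      z[k, ] <- sqrt(1 - w_hf) * core / stats::sd(core) +
        sqrt(w_hf) * hf / stats::sd(hf)
    }
    if (spec$regularity > 0) {
      rho <- spec$regularity
      tt <- seq_len(n) / fs
      for (k in 1:2) {
        osc <- sqrt(2) * sin(2 * pi * fc * tt + stats::runif(1L, 0, 2 * pi))
        z[k, ] <- sqrt(1 - rho^2) * z[k, ] + rho * osc
      }
    }
    z <- z - rowMeans(z)
    # exact coloring: whiten against the realized covariance, then apply
    # the symmetric square root of the target
    cz <- tcrossprod(z) / (n - 1L)
    ez <- eigen(cz, symmetric = TRUE)
    wh <- ez$vectors %*% diag(1 / sqrt(pmax(ez$values, 1e-300))) %*% t(ez$vectors)
    et <- eigen(spec$covariance, symmetric = TRUE)
    col <- et$vectors %*% diag(sqrt(pmax(et$values, 0))) %*% t(et$vectors)
    y <- col %*% wh %*% z
    cop_trial(y[1, ], y[2, ], spec$fs, ...)
  })
}

#' Matrix of independent null p-values
#'
#' i.i.d. Uniform(0, 1) draws arranged as `n_sim` replicates of `m`
#' hypotheses, for calibrating multiple-testing procedures.
#'
#' @param m hypotheses per replicate.
#' @param n_sim number of replicates.
#' @param seed integer seed.
#' @return `n_sim` x `m` numeric matrix.
#' @export
gen_null_pvalues <- function(m, n_sim, seed = 1L) {
  if (m < 1L || n_sim < 1L) abort_param("`m` and `n_sim` must be >= 1")
  with_seed(seed, matrix(stats::runif(n_sim * m), n_sim, m))
}
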