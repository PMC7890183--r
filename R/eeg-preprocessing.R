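# EEG preprocessing chain: broadband zero-phase FIR filtering, bipolar
# EOG derivation, regression-based ocular correction, epoching,
# amplitude-based artifact rejection, and sub-band filtering.
# The pipeline order is fixed: broadband -> ocular regression -> epoch
# -> reject -> band filter.

#' Canonical analysis sub-bands
#'
#' theta 4--8 Hz, alpha 8--13 Hz, beta 13--20 Hz. Oscillations below
#' 4 Hz and above 20 Hz are excluded from connectivity analysis (ocular
#' and muscle contamination).
#'
#' @return named list of band edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 20))
}

#' Broadband zero-phase FIR filter
#'
#' Band-pass between `band[1]` and `band[2]` with a linear-phase FIR
#' (Blackman design) applied with group-delay compensation, so the net
#' phase response is zero. The steep low edge removes DC drift: a
#' constant offset is attenuated by more than 60 dB.
#'
#' @param rec an [eeg_recording()].
#' @param band passband edges in Hz (default `c(1, 60)`).
#' @param transition_hz transition width of the design (default 0.6 Hz).
#' @return filtered [eeg_recording()] (EOG channels filtered alike).
#' @export
broadband_filter <- function(rec, band = c(1, 60), transition_hz = 0.6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * band[2])
    abort_param("sampling rate too low for the requested band")
  if (band[1] <= 0 || band[2] <= band[1])
    abort_param("`band` must be increasing positive edges within Nyquist")
  n <- ncol(rec$data)
  b <- fir_bandpass_design(rec$fs, band, transition_hz,
                           max_taps = 2L * ((n - 1L) %/% 2L) + 1L)
  out <- rec
  for (c in seq_len(nrow(out$data)))
    out$data[c, ] <- fir_zero_phase(rec$data[c, ], b)
  if (!is.null(out$eog))
    for (c in seq_len(nrow(out$eog)))
      out$eog[c, ] <- fir_zero_phase(rec$eog[c, ], b)
  out
}

#' Derive bipolar EOG channels
#'
#' Vertical EOG is the supraorbital minus the infraorbital electrode;
#' horizontal EOG is the right minus the left outer-canthus electrode.
#'
#' @param rec an [eeg_recording()] with the four periocular channels
#'   attached (`supra`, `infra`, `left`, `right`).
#' @return list with numeric series `veog` and `heog`.
#' @export
derive_eog <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$eog)) abort_param("recording has no periocular channels")
  need <- c("supra", "infra", "left", "right")
  missing <- setdiff(need, rownames(rec$eog))
  if (length(missing))
    abort_param(paste0("missing periocular channel(s): ",
                       paste(missing, collapse = ", ")))
  list(veog = rec$eog["supra", ] - rec$eog["infra", ],
       heog = rec$eog["right", ] - rec$eog["left", ])
}

#' Regression-based ocular artifact correction
#'
#' Each scalp channel is regressed (ordinary least squares with an
#' intercept) on the bipolar VEOG and HEOG traces; the fitted ocular
#' components `b_v * veog + b_h * heog` are subtracted. Coefficients are
#' returned in the `ocular_coefficients` attribute for recovery checks
#' against planted propagation gains.
#'
#' @param rec an [eeg_recording()].
#' @param veog,heog bipolar EOG series, time-aligned with `rec`.
#' @return corrected [eeg_recording()] with attribute
#'   `ocular_coefficients` (channels x 2 matrix, columns `b_v`, `b_h`).
#' @export
regress_out_ocular <- function(rec, veog, heog) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  if (length(veog) != n || length(heog) != n)
    abort_param("EOG series must be time-aligned with the recording")
  degenerate <- stats::sd(veog) == 0 || stats::sd(heog) == 0
  collinear <- !degenerate && abs(stats::cor(veog, heog)) > 0.999
  x <- cbind(intercept = 1, veog = veog, heog = heog)
  if (collinear) warning("VEOG and HEOG are collinear; using a pseudo-inverse fit")
  if (collinear || degenerate) {
    xtx_inv <- MASS::ginv(crossprod(x))
  } else {
    xtx_inv <- solve(crossprod(x))
  }
  beta <- xtx_inv %*% crossprod(x, t(rec$data))  # 3 x channels
  out <- rec
  out$data <- rec$data - t(x[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE])
  coefs <- t(beta[-1, , drop = FALSE])
  dimnames(coefs) <- list(rec$labels, c("b_v", "b_h"))
  attr(out, "ocular_coefficients") <- coefs
  out
}

#' A set of fixed-length EEG epochs
#'
#' @param epochs list of channels x samples matrices, all equal shape.
#' @param fs sampling rate, Hz.
#' @param labels channel labels.
#' @param band band label: `"none"`, `"theta"`, `"alpha"`, or `"beta"`.
#' @param mask data frame (`epoch`, `kept`, `reason`) recording
#'   rejection decisions.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, labels, band = "none", mask = NULL) {
  if (!length(epochs)) abort_param("no epochs")
  dims <- vapply(epochs, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_param("all epochs must share one shape")
  if (is.null(mask))
    mask <- data.frame(epoch = seq_along(epochs), kept = TRUE, reason = "",
                       stringsAsFactors = FALSE)
  structure(list(epochs = epochs, fs = fs, labels = labels,
                 band = band, mask = mask),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %d samples @ %g Hz, band %s\n",
              length(x$epochs), sum(x$mask$kept), nrow(x$epochs[[1]]),
              ncol(x$epochs[[1]]), x$fs, x$band))
  invisible(x)
}

# Epochs that survived rejection.
kept_epochs <- function(eps) eps$epochs[eps$mask$kept]

#' Segment a recording into fixed-length epochs
#'
#' Contiguous non-overlapping segments after discarding the unstable
#' head of the run; any remainder tail is dropped. Pure sample-index
#' arithmetic, no resampling.
#'
#' @param rec an [eeg_recording()].
#' @param length_s epoch length in seconds (default 2).
#' @param discard_head_s seconds discarded from the start (default 2).
#' @return an [epoch_set()] with band `"none"`.
#' @export
epoch_recording <- function(rec, length_s = 2, discard_head_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  len <- round(length_s * rec$fs)
  head_n <- round(discard_head_s * rec$fs)
  n_ep <- (n - head_n) %/% len
  if (n_ep < 1L)
    abort_param("recording shorter than the discarded head plus one epoch")
  eps <- lapply(seq_len(n_ep), function(k) {
    idx <- head_n + (k - 1L) * len + seq_len(len)
    rec$data[, idx, drop = FALSE]
  })
  epoch_set(eps, rec$fs, rec$labels)
}

#' Amplitude-threshold artifact rejection
#'
#' An epoch is dropped iff any scalp channel contains a sample whose
#' absolute amplitude exceeds the threshold. The rejection mask records
#' the reason per epoch.
#'
#' @param eps an [epoch_set()].
#' @param amp_threshold_uV rejection threshold in microvolts (default 100).
#' @return the [epoch_set()] with an updated mask.
#' @export
reject_artifacts <- function(eps, amp_threshold_uV = 100) {
  stopifnot(inherits(eps, "epoch_set"))
  over <- vapply(eps$epochs, function(e) max(abs(e)) > amp_threshold_uV,
                 logical(1L))
  mask <- eps$mask
  mask$kept <- mask$kept & !over
  mask$reason[over] <- sprintf("amplitude > %g uV", amp_threshold_uV)
  if (!any(mask$kept))
    abort("all epochs rejected; review the amplitude threshold",
          class = "posturenet_rejection_error")
  eps$mask <- mask
  eps
}

#' Filter epochs into a named frequency sub-band
#'
#' 4th-order Butterworth applied forward-backward per epoch, with 0.5 s
#' reflection padding trimmed after filtering to bound edge transients
#' on short epochs.
#'
#' @param eps an [epoch_set()].
#' @param band_label `"theta"`, `"alpha"`, or `"beta"`.
#' @return the band-limited [epoch_set()] with the band recorded.
#' @export
band_filter <- function(eps, band_label) {
  stopifnot(inherits(eps, "epoch_set"))
  bands <- eeg_bands()
  if (!band_label %in% names(bands))
    abort_param(paste0("unknown band label '", band_label, "'; expected ",
                       paste(names(bands), collapse = ", ")))
  edges <- bands[[band_label]]
  out <- eps
  out$epochs <- lapply(eps$epochs, function(e) {
    t(apply(e, 1L, butter_filtfilt, fs = eps$fs, w = edges, type = "pass"))
  })
  out$band <- band_label
  out
}

#' Full preprocessing chain for one recording
#'
#' broadband filter -> EOG derivation and regression -> epoching ->
#' amplitude rejection. Band filtering is applied afterwards per band of
#' interest with [band_filter()].
#'
#' @param rec an [eeg_recording()] with periocular channels.
#' @param broadband passband for the broadband stage, Hz.
#' @param epoch_s epoch length, seconds.
#' @param discard_head_s discarded head, seconds.
#' @param amp_threshold_uV rejection threshold, microvolts.
#' @return an [epoch_set()] (band `"none"`).
#' @export
preprocess_eeg <- function(rec, broadband = c(1, 60), epoch_s = 2,
                           discard_head_s = 2, amp_threshold_uV = 100) {
  rec <- broadband_filter(rec, band = broadband)
  if (!is.null(rec$eog)) {
    eog <- derive_eog(rec)
    rec <- regress_out_ocular(rec, eog$veog, eog$heog)
  }
  eps <- epoch_recording(rec, length_s = epoch_s,
                         discard_head_s = discard_head_s)
  reject_artifacts(eps, amp_threshold_uV)
}
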