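# Shared signal-processing primitives: analytic signal, Welch PSD,
# zero-phase filtering helpers, seeded-RNG scoping, condition helpers.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so generators are
#' reproducible without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Error with condition classes so callers can distinguish parameter
# errors from mathematically undefined results.
abort <- function(msg, class = "posturenet_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "posturenet_error", "error", "condition")))
}

abort_param <- function(msg) abort(msg, class = "posturenet_parameter_error")
abort_undefined <- function(msg) abort(msg, class = "posturenet_undefined_error")

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes negative frequencies and doubles positive ones, the standard
#' FFT construction of the analytic signal whose argument is the
#' instantaneous phase and whose modulus is the envelope.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) abort_param("`x` must be a numeric vector of length >= 2")
  if (any(!is.finite(x))) abort_param("`x` contains non-finite samples")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Analytic signal of each row of a channels x samples matrix.
analytic_rows <- function(mat) {
  t(apply(mat, 1L, analytic_signal))
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper. Segments are
#' mean-removed, tapered, and zero-padded to `nfft` points when a finer
#' frequency grid than `1/window_s` is requested via `resolution_hz`.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds (default 15 s).
#' @param overlap_fraction overlap between successive segments as a
#'   fraction of the window length (default 0.25).
#' @param resolution_hz optional target spacing of the frequency grid in
#'   Hz; achieved by zero-padding the tapered segments.
#' @return data frame with columns `freq` (Hz) and `power` (one-sided PSD).
#' @export
welch_psd <- function(x, fs, window_s = 15, overlap_fraction = 0.25,
                      resolution_hz = NULL) {
  nwin <- round(window_s * fs)
  if (nwin < 8L) abort_param("window too short for a spectral estimate")
  if (length(x) < nwin) abort_param("series shorter than one Welch window")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort_param("`overlap_fraction` must be in [0, 1)")
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  nfft <- nwin
  if (!is.null(resolution_hz)) nfft <- max(nfft, ceiling(fs / resolution_hz))
  k <- seq_len(nwin) - 1L
  win <- 0.5 * (1 - cos(2 * pi * k / (nwin - 1L)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  nbins <- floor(nfft / 2) + 1L
  acc <- numeric(nbins)
  u <- sum(win^2)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * win
    spec <- stats::fft(c(seg, numeric(nfft - nwin)))
    acc <- acc + Mod(spec[seq_len(nbins)])^2 / (fs * u)
  }
  pow <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when present)
  scale <- rep(2, nbins)
  scale[1L] <- 1
  if (nfft %% 2L == 0L) scale[nbins] <- 1
  data.frame(freq = (seq_len(nbins) - 1L) * fs / nfft, power = pow * scale)
}

# Odd (point-symmetric) reflection padding, the same boundary rule
# filtfilt uses; keeps constants constant and slopes continuous.
pad_reflect <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  if (p < 1L) return(x)
  left <- 2 * x[1L] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  c(left, x, right)
}

# Linear-phase FIR band-pass (Blackman window). Tap count set by the
# requested transition width; capped to the signal length by callers.
fir_bandpass_design <- function(fs, band, transition_hz, max_taps = NULL) {
  ntaps <- ceiling(5.5 * fs / transition_hz)
  if (!is.null(max_taps)) ntaps <- min(ntaps, max_taps)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  ntaps <- max(ntaps, 33L)
  signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass",
               window = signal::blackman(ntaps))
}

# Even (mirror) reflection padding: value-continuous and mean-preserving,
# the right boundary rule for band-pass filters where an odd reflection
# would inject a local-mean step into the passband.
pad_mirror <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  if (p < 1L) return(x)
  c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
}

# Apply a symmetric (linear-phase) FIR with group-delay compensation via
# FFT convolution: exactly zero net phase for a type-I filter.
fir_zero_phase <- function(x, b) {
  n <- length(x)
  L <- length(b)
  half <- (L - 1L) %/% 2L
  xp <- pad_mirror(x, min(n - 1L, L))
  p <- (length(xp) - n) %/% 2L
  m <- length(xp) + L - 1L
  nfft <- stats::nextn(m, 2L)
  conv <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                          stats::fft(c(b, numeric(nfft - L))), inverse = TRUE)) / nfft
  # full convolution index of input sample k is k + half after delay
  conv[(p + half + 1L):(p + half + n)]
}

# Squared magnitude response of an IIR filter at frequencies f (Hz).
filter_mag2 <- function(flt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(flt$b * zz^(seq_along(flt$b) - 1L)),
                complex(1L))
  den <- vapply(z, function(zz) sum(flt$a * zz^(seq_along(flt$a) - 1L)),
                complex(1L))
  Mod(num / den)^2
}

# Centroid of the forward-backward (|H|^4) response over (0, fmax] with
# a white-noise input: the theoretical mean frequency of the filtered
# process restricted to the analysis band.
filter_band_centroid <- function(flt, fs, fmax = 6) {
  f <- seq(0.002, fmax, by = 0.002)
  p <- filter_mag2(flt, f, fs)^2
  sum(f * p) / sum(p)
}

# Zero-phase Butterworth with reflection padding trimmed afterwards.
# The generous default padding absorbs filtfilt startup transients.
butter_filtfilt <- function(x, fs, w, type, order = 4L, pad_s = 2) {
  flt <- signal::butter(order, w / (fs / 2), type)
  p <- min(length(x) - 1L, round(pad_s * fs))
  xp <- pad_reflect(x, p)
  p <- (length(xp) - length(x)) %/% 2L
  y <- signal::filtfilt(flt, xp)
  y[(p + 1L):(p + length(x))]
}

#' The 30-channel scalp montage used throughout the package
#'
#' Standard 10--20 site labels for the 30 scalp electrodes; synthetic
#' recordings with up to 30 channels take their labels from this list.
#'
#' @return character vector of 30 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "FT7", "FT8",
    "FCz", "FC3", "FC4", "Cz", "C3", "C4", "CPz", "CP3", "CP4",
    "Pz", "P3", "P4", "T3", "T4", "T5", "T6", "TP7", "TP8",
    "Oz", "O1", "O2")
}
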