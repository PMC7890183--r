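# Phase-lag based functional connectivity: instantaneous phase via the
# analytic signal, the phase-lag index (PLI), and the weighted phase-lag
# index (wPLI), per epoch and frequency band.

#' Instantaneous phase of a band-limited epoch
#'
#' Analytic-signal phase per channel. The first and last 10% of samples
#' are flagged for exclusion from expectations because the
#' finite-length Hilbert transform is biased near the edges. An all-zero
#' channel has undefined phase and is flagged; connectivity entries
#' involving it are set missing.
#'
#' @param epoch channels x samples numeric matrix (band-limited).
#' @param edge_fraction fraction of samples flagged at each edge
#'   (default 0.1).
#' @return an object of class `phase_series`: list with `phi` (wrapped
#'   phase, channels x samples), `analytic` (complex matrix), `interior`
#'   (logical sample mask), `bad` (logical channel mask).
#' @export
instantaneous_phase <- function(epoch, edge_fraction = 0.1) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  bad <- apply(epoch, 1L, function(x) all(x == 0))
  a <- matrix(complex(real = 0), nrow(epoch), n)
  for (c in seq_len(nrow(epoch)))
    if (!bad[c]) a[c, ] <- analytic_signal(epoch[c, ])
  phi <- wrap_phase(Arg(a))
  phi[bad, ] <- NA_real_
  edge <- floor(edge_fraction * n)
  interior <- rep(TRUE, n)
  if (edge > 0L) interior[c(seq_len(edge), n - seq_len(edge) + 1L)] <- FALSE
  structure(list(phi = phi, analytic = a, interior = interior, bad = bad),
            class = "phase_series")
}

#' Phase-lag index of two phase series
#'
#' `PLI = |mean(sign(dphi))|` with `dphi` the wrapped phase difference:
#' the asymmetry of the phase-difference distribution about zero.
#' Insensitive to zero-lag (volume-conducted) coupling, which puts mass
#' exactly at `dphi = 0`.
#'
#' @param phix,phiy phase series in radians, equal length (already
#'   restricted to interior samples).
#' @return scalar in `[0, 1]`.
#' @export
pli <- function(phix, phiy) {
  if (length(phix) != length(phiy)) abort_param("phase series lengths differ")
  if (!length(phix)) abort_param("empty phase series")
  dphi <- wrap_phase(phix - phiy)
  abs(mean(sign(dphi)))
}

#' Weighted phase-lag index of two band-limited series
#'
#' Default (`variant = "cross-spectrum"`): with `Z` the sample
#' cross-spectrum `a_x * Conj(a_y)` of the analytic signals,
#' `wPLI = |mean(Im Z)| / mean(|Im Z|)`. Phase differences near ±90°
#' receive maximal weight and zero-lag components (real-valued `Z`)
#' contribute nothing, suppressing volume conduction. The
#' `"phase-weighted"` variant drops the amplitude weighting and weights
#' by the magnitude of the wrapped phase difference itself:
#' `|mean(|dphi| * sign(dphi))| / mean(|dphi|)`.
#'
#' An exactly zero-lag pair has a vanishing denominator; the index is
#' then defined as 0 (no phase synchronization).
#'
#' @param x,y real band-limited series of equal length, or a
#'   precomputed [instantaneous_phase()] pair via [wpli_from_analytic()].
#' @param variant `"cross-spectrum"` (default) or `"phase-weighted"`.
#' @param edge_fraction fraction of samples dropped at each edge before
#'   averaging (default 0.1).
#' @return scalar in `[0, 1]`.
#' @export
wpli <- function(x, y, variant = c("cross-spectrum", "phase-weighted"),
                 edge_fraction = 0.1) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) abort_param("series lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_param("non-finite input series")
  ax <- analytic_signal(x)
  ay <- analytic_signal(y)
  n <- length(x)
  edge <- floor(edge_fraction * n)
  idx <- if (edge > 0L) (edge + 1L):(n - edge) else seq_len(n)
  wpli_from_analytic(ax[idx], ay[idx], variant)
}

#' wPLI from precomputed analytic signals
#'
#' @param ax,ay complex analytic-signal vectors (interior samples).
#' @param variant see [wpli()].
#' @return scalar in `[0, 1]`.
#' @export
wpli_from_analytic <- function(ax, ay,
                               variant = c("cross-spectrum", "phase-weighted")) {
  variant <- match.arg(variant)
  if (variant == "cross-spectrum") {
    imz <- Im(ax * Conj(ay))
    den <- mean(abs(imz))
    if (!is.finite(den) || den < 1e-12) return(0)
    abs(mean(imz)) / den
  } else {
    dphi <- wrap_phase(Arg(ax) - Arg(ay))
    den <- mean(abs(dphi))
    if (!is.finite(den) || den < 1e-12) return(0)
    abs(mean(abs(dphi) * sign(dphi))) / den
  }
}

#' Connectivity matrix object
#'
#' @param w symmetric node x node matrix in `[0, 1]`, zero diagonal.
#' @param method `"wpli"` or `"pli"`.
#' @param band band label.
#' @param epoch_id source epoch index.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix_obj <- function(w, method, band = "none", epoch_id = NA) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) abort_param("connectivity matrix must be square")
  structure(list(w = w, method = method, band = band, epoch_id = epoch_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, band %s, %d nodes, epoch %s\n",
              x$method, x$band, nrow(x$w), as.character(x$epoch_id)))
  invisible(x)
}

#' All-pairs connectivity per kept epoch
#'
#' Computes PLI or wPLI between every unordered channel pair of each
#' kept epoch of a band-limited epoch set. Pairs involving an all-zero
#' (undefined-phase) channel are set to `NA`.
#'
#' @param eps a band-limited [epoch_set()].
#' @param method `"wpli"` (default) or `"pli"`.
#' @param variant wPLI estimator variant, see [wpli()].
#' @param edge_fraction per-side edge exclusion for Hilbert transients.
#' @return list of [connectivity_matrix_obj()], one per kept epoch.
#' @export
connectivity_matrices <- function(eps, method = c("wpli", "pli"),
                                  variant = c("cross-spectrum", "phase-weighted"),
                                  edge_fraction = 0.1) {
  stopifnot(inherits(eps, "epoch_set"))
  method <- match.arg(method)
  variant <- match.arg(variant)
  kept <- which(eps$mask$kept)
  if (!length(kept)) abort_param("no kept epochs")
  lapply(kept, function(k) {
    e <- eps$epochs[[k]]
    ph <- instantaneous_phase(e, edge_fraction)
    nch <- nrow(e)
    idx <- which(ph$interior)
    w <- matrix(0, nch, nch, dimnames = list(eps$labels, eps$labels))
    for (i in seq_len(nch - 1L)) {
      for (j in (i + 1L):nch) {
        v <- if (ph$bad[i] || ph$bad[j]) {
          NA_real_
        } else if (method == "wpli") {
          wpli_from_analytic(ph$analytic[i, idx], ph$analytic[j, idx], variant)
        } else {
          pli(ph$phi[i, idx], ph$phi[j, idx])
        }
        w[i, j] <- w[j, i] <- v
      }
    }
    connectivity_matrix_obj(w, method, eps$band, k)
  })
}
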