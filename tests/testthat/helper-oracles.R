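# Independent oracle implementations used across the suite. These stay
# deliberately naive (double loops, exhaustive enumeration, direct
# formulas) so they share no code path with the package.

# O(N^2) template-counting sample entropy: direct double loop over all
# ordered template pairs i != j, Chebyshev distance, self-matches
# excluded, counts over i = 1..N-m as in the defining formula.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a <- 0
  b <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      db <- max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)]))
      if (db <= r) {
        b <- b + 1
        da <- max(db, abs(x[i + m] - x[j + m]))
        if (da <= r) a <- a + 1
      }
    }
  }
  -log(a / b)
}

# Decode a Pruefer sequence into the edge matrix of a labeled tree.
prufer_to_edges <- function(p, n) {
  deg <- rep(1L, n)
  for (v in p) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  avail <- rep(TRUE, n)
  for (k in seq_along(p)) {
    v <- p[k]
    leaf <- which(deg == 1L & avail)[1L]
    edges[k, ] <- c(min(leaf, v), max(leaf, v))
    avail[leaf] <- FALSE
    deg[leaf] <- 0L
    deg[v] <- deg[v] - 1L
  }
  last <- which(avail & deg == 1L)
  edges[n - 1L, ] <- c(min(last), max(last))
  edges
}

# All labeled trees on n nodes (n^(n-2) of them) as a list of edge
# matrices, via exhaustive Pruefer enumeration.
all_labeled_trees <- function(n) {
  if (n == 2L) return(list(matrix(c(1L, 2L), 1L, 2L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(k) prufer_to_edges(seqs[k, ], n))
}

# Hop-distance matrix of a tree given as an edge matrix (Floyd-Warshall).
oracle_tree_distances <- function(edges, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    d[edges[k, 1], edges[k, 2]] <- 1
    d[edges[k, 2], edges[k, 1]] <- 1
  }
  for (v in seq_len(n)) d <- pmin(d, outer(d[, v], d[v, ], `+`))
  d
}

# The four normalized tree metrics from first principles: BFS/FW
# distances for diameter and eccentricity, degree counts for leaves,
# and pair-path enumeration (a path a-b passes v iff
# d(a,v) + d(v,b) = d(a,b)) for betweenness.
oracle_tree_metrics <- function(edges, n) {
  d <- oracle_tree_distances(edges, n)
  deg <- tabulate(as.integer(edges), nbins = n)
  btw <- vapply(seq_len(n), function(v) {
    cnt <- 0L
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (a != v && b != v && d[a, v] + d[v, b] == d[a, b]) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1L))
  c(diameter = max(d) / (n - 1),
    leaf_fraction = sum(deg == 1L) / (n - 1),
    avg_eccentricity = mean(apply(d, 1L, max)) / (n - 1),
    bc_max = max(btw) / ((n - 1) * (n - 2) / 2))
}

# Build a spanning_tree object directly from an oracle edge matrix.
tree_from_edges <- function(edges, n) {
  ord <- order(edges[, 1], edges[, 2])
  spanning_tree(as.character(seq_len(n)),
                data.frame(i = edges[ord, 1], j = edges[ord, 2],
                           weight = rep(1, n - 1L)))
}

# Independent FFT Hilbert: explicit positive/negative frequency masks,
# a different construction from the package's doubling vector.
oracle_analytic <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  freq <- seq_len(n) - 1L
  pos <- freq >= 1 & freq < n / 2
  neg <- freq > n / 2
  f[pos] <- 2 * f[pos]
  f[neg] <- 0
  stats::fft(f, inverse = TRUE) / n
}

# Direct periodogram spectral centroid over (0, fmax].
oracle_centroid <- function(x, fs, fmax = 6) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x)[seq_len(floor(n / 2) + 1L)])^2
  f <- (seq_along(p) - 1L) * fs / n
  keep <- f > 0 & f <= fmax
  sum(f[keep] * p[keep]) / sum(p[keep])
}

# A bivariate sample whose *sample* covariance equals `sigma` exactly.
sample_with_exact_cov <- function(n, sigma, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), 2L, n)
  z <- z - rowMeans(z)
  cz <- tcrossprod(z) / (n - 1)
  wh <- solve(chol(cz))
  y <- t(chol(sigma)) %*% t(wh) %*% z
  list(x = y[1, ], y = y[2, ])
}

# Small synthetic epoch set used by preprocessing/connectivity tests.
make_epochs <- function(mats, fs = 200, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(mats[[1]])))
  epoch_set(mats, fs = fs, labels = labels)
}
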