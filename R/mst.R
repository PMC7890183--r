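# Spanning-tree backbone of a connectivity matrix and the four
# network-integration metrics: normalized diameter, leaf fraction,
# normalized average eccentricity, and normalized maximal betweenness.
# The "minimum spanning tree" of a synchrony matrix follows the field's
# convention: the tree of the strongest connections, i.e. the
# maximum-weight spanning tree (equivalently the MST of 1 - w).

#' Spanning tree object
#'
#' @param nodes node labels.
#' @param edges data frame with columns `i`, `j` (1-based node indices,
#'   `i < j`) and `weight`.
#' @return an object of class `spanning_tree`.
#' @export
spanning_tree <- function(nodes, edges) {
  n <- length(nodes)
  if (nrow(edges) != n - 1L) abort_param("a spanning tree has exactly N - 1 edges")
  structure(list(nodes = nodes, edges = edges), class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total weight %.4g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Kruskal's algorithm on edges sorted by descending weight, ties broken
#' deterministically by lexicographic `(i, j)` order (weights compared
#' exactly, no epsilon). Zero-weight edges are used only when the
#' positive-weight graph alone cannot span all nodes (with a warning);
#' `NA` entries (undefined-phase channels) are treated as zero, also
#' with a warning.
#'
#' @param w a [connectivity_matrix_obj()] or a symmetric non-negative
#'   numeric matrix.
#' @return a [spanning_tree()].
#' @export
max_spanning_tree <- function(w) {
  if (inherits(w, "connectivity_matrix")) w <- w$w
  w <- as.matrix(w)
  n <- nrow(w)
  if (n < 2L) abort_param("at least 2 nodes required")
  if (ncol(w) != n) abort_param("matrix must be square")
  if (anyNA(w)) {
    warning("NA connectivity entries treated as zero weight")
    w[is.na(w)] <- 0
  }
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    abort_param("matrix must be symmetric")
  if (min(w) < 0) abort_param("weights must be non-negative")
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ei <- ut[, 1L]
  ej <- ut[, 2L]
  ew <- w[ut]
  ord <- order(-ew, ei, ej)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  take <- logical(length(ord))
  n_edges <- 0L
  used_zero <- FALSE
  for (k in ord) {
    if (n_edges == n - 1L) break
    ra <- find(ei[k])
    rb <- find(ej[k])
    if (ra != rb) {
      parent[ra] <- rb
      take[k] <- TRUE
      n_edges <- n_edges + 1L
      if (ew[k] == 0) used_zero <- TRUE
    }
  }
  if (used_zero)
    warning("positive-weight edges do not span all nodes; zero edges included")
  sel <- which(take)
  sel <- sel[order(ei[sel], ej[sel])]
  spanning_tree(labels,
                data.frame(i = ei[sel], j = ej[sel], weight = ew[sel]))
}

# adjacency list of a spanning tree
tree_adjacency <- function(t) {
  n <- length(t$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(t$edges))) {
    i <- t$edges$i[k]
    j <- t$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# all-pairs hop distances via BFS from every node
tree_distances <- function(t) {
  n <- length(t$nodes)
  adj <- tree_adjacency(t)
  d <- matrix(0L, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0L)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (dist[u] < 0L) {
            dist[u] <- dist[v] + 1L
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Normalized tree diameter
#'
#' Longest shortest path in edge counts, divided by the edge count
#' `M = N - 1`, so a path graph scores 1 and a star `2 / (N - 1)`.
#' Lower values indicate a more integrated (star-like) network.
#'
#' @param t a [spanning_tree()].
#' @return scalar in `(0, 1]`.
#' @export
tree_diameter <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  max(tree_distances(t)) / (length(t$nodes) - 1L)
}

#' Leaf fraction
#'
#' Number of degree-1 nodes divided by the maximum possible `N - 1`
#' (attained by a star). Higher values indicate integration.
#'
#' @param t a [spanning_tree()].
#' @return scalar in `(0, 1]`.
#' @export
leaf_fraction <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- length(t$nodes)
  deg <- tabulate(c(t$edges$i, t$edges$j), nbins = n)
  sum(deg == 1L) / (n - 1L)
}

#' Normalized average eccentricity
#'
#' Mean over nodes of the longest hop distance to any other node,
#' divided by `N - 1`. Lower values indicate integration.
#'
#' @param t a [spanning_tree()].
#' @return scalar in `(0, 1]`.
#' @export
avg_eccentricity <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  d <- tree_distances(t)
  mean(apply(d, 1L, max)) / (length(t$nodes) - 1L)
}

#' Normalized maximal betweenness centrality
#'
#' For each node, the number of node pairs whose unique tree path passes
#' through it (endpoints excluded), maximized over nodes and divided by
#' `(N - 1)(N - 2) / 2` (the star-center value). Higher values indicate
#' a stronger hub.
#'
#' @param t a [spanning_tree()].
#' @return scalar in `[0, 1]`.
#' @export
bc_max <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- length(t$nodes)
  if (n < 3L) abort_param("betweenness needs at least 3 nodes")
  adj <- tree_adjacency(t)
  best <- 0
  for (v in seq_len(n)) {
    # component sizes of the forest after removing v; pairs through v
    # are products of sizes of distinct components
    seen <- rep(FALSE, n)
    seen[v] <- TRUE
    sizes <- integer(0L)
    for (u in adj[[v]]) {
      if (seen[u]) next
      size <- 0L
      frontier <- u
      seen[u] <- TRUE
      while (length(frontier)) {
        size <- size + length(frontier)
        nxt <- integer(0L)
        for (a in frontier) {
          for (b in adj[[a]]) {
            if (!seen[b]) {
              seen[b] <- TRUE
              nxt <- c(nxt, b)
            }
          }
        }
        frontier <- nxt
      }
      sizes <- c(sizes, size)
    }
    through <- (sum(sizes)^2 - sum(sizes^2)) / 2
    if (through > best) best <- through
  }
  best / ((n - 1) * (n - 2) / 2)
}

#' All four integration metrics of one tree
#'
#' @param t a [spanning_tree()].
#' @return one-row data frame: `diameter`, `leaf_fraction`,
#'   `avg_eccentricity`, `bc_max`.
#' @export
tree_metrics <- function(t) {
  data.frame(diameter = tree_diameter(t),
             leaf_fraction = leaf_fraction(t),
             avg_eccentricity = avg_eccentricity(t),
             bc_max = bc_max(t))
}

#' Average tree metrics over epochs, then over trials
#'
#' Given per-epoch trees of one trial (a flat list) the metrics are
#' averaged arithmetically over epochs. Given a list of trials (a list
#' of per-epoch lists) each trial is averaged first and the per-trial
#' means are then averaged, so trials with unequal epoch counts carry
#' equal weight.
#'
#' @param trees a list of [spanning_tree()] (one trial) or a list of
#'   such lists (several trials).
#' @return one-row data frame of averaged metrics.
#' @export
aggregate_metrics <- function(trees) {
  if (!length(trees)) abort_param("no trees to aggregate")
  if (inherits(trees[[1]], "spanning_tree")) {
    rows <- do.call(rbind, lapply(trees, tree_metrics))
    as.data.frame(t(colMeans(rows)))
  } else {
    per_trial <- do.call(rbind, lapply(trees, aggregate_metrics))
    as.data.frame(t(colMeans(per_trial)))
  }
}
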