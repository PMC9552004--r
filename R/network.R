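# Edge ranking shared by spanning_threshold() and binarize(): weight
# descending, ties broken by (row, column) lexicographic order so that
# thresholding is deterministic and monotone in density.
ranked_edges <- function(W) {
  n <- nrow(W)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  w <- W[cbind(i, j)]
  ord <- order(-w, i, j)
  data.frame(i = i[ord], j = j[ord], w = w[ord])
}

#' Minimally spanning edge density of a connectivity matrix
#'
#' The smallest edge density `d` such that keeping the top `d` fraction of
#' off-diagonal weights yields a connected graph. Used to set each
#' participant's per-band binarization threshold from the mean baseline wPLI
#' matrix.
#'
#' @param W Symmetric non-negative connectivity matrix.
#' @return Density in `(0, 1]` (number of kept edges / number of node pairs).
#' @export
spanning_threshold <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- NA
  if (any(apply(off, 1, function(r) all(r[!is.na(r)] == 0)))) {
    stop("matrix has an all-zero row; graph cannot be connected")
  }
  edges <- ranked_edges(W)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  n_comp <- n
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$i[k])
    rj <- find(edges$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      n_comp <- n_comp - 1
      if (n_comp == 1) return(k / nrow(edges))
    }
  }
  stop("graph cannot be connected")  # unreachable after the all-zero check
}

#' Binarize a connectivity matrix at a given edge density
#'
#' The top `ceiling(density * n_pairs)` off-diagonal weights become 1, the
#' rest 0 (ties broken by (row, column) order).
#'
#' @param W Symmetric connectivity matrix.
#' @param density Proportion of edges to keep, in `(0, 1]`.
#' @return Binary symmetric matrix with zero diagonal; attribute
#'   `kind = "binary"`.
#' @export
binarize <- function(W, density) {
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  edges <- ranked_edges(W)
  keep <- seq_len(ceiling(density * nrow(edges)))
  B <- matrix(0, nrow(W), ncol(W))
  B[cbind(edges$i[keep], edges$j[keep])] <- 1
  B[cbind(edges$j[keep], edges$i[keep])] <- 1
  attr(B, "kind") <- "binary"
  B
}

#' Random surrogate networks preserving the degree sequence
#'
#' Generates surrogates by double-edge swaps (Maslov-Sneppen rewiring). For
#' weighted graphs the original edge weights are additionally permuted over
#' the rewired topology, preserving the degree sequence exactly and the
#' strength distribution approximately. A complete graph admits no swaps and
#' yields surrogates with identical topology.
#'
#' @param W Symmetric adjacency matrix (binary or weighted).
#' @param n Number of surrogates (default 100).
#' @param weighted Permute weights over the rewired edges; by default `TRUE`
#'   when `W` contains values other than 0/1.
#' @param seed Optional integer seed.
#' @param swap_factor Swap attempts per edge (default 10).
#' @return List of `n` surrogate matrices.
#' @export
random_ensemble <- function(W, n = 100, weighted = NULL, seed = NULL,
                            swap_factor = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weighted)) weighted <- !all(W %in% c(0, 1))
  ne <- sum(W[upper.tri(W)] > 0)
  if (ne < 2) stop("graph has no swappable edge pairs")
  lapply(seq_len(n), function(s) {
    R <- cpp_rewire(W, swap_factor * ne)
    if (weighted) {
      up <- upper.tri(R) & R > 0
      w <- W[upper.tri(W) & W > 0]
      R[up] <- sample(w)
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
    }
    R
  })
}

# raw metrics of one graph as a named vector
raw_graph_metrics <- function(W, restarts = 10) {
  m <- cpp_graph_metrics(W, restarts)
  if (!is.finite(m[["pathlen"]])) stop("graph is disconnected")
  m
}

#' Graph-theory metrics with random-network normalization
#'
#' Computes characteristic path length (mean shortest path, edge length
#' `1/weight`), mean clustering coefficient (geometric-mean-of-triangle-weights
#' form, reducing to the usual binary coefficient on 0/1 graphs), modularity
#' (best of `restarts` Louvain runs) and mean node strength (degree for
#' binary graphs), plus each metric divided by its mean over an ensemble of
#' degree-preserving random surrogates, and the small-worldness ratio
#' (normalized clustering / normalized path length).
#'
#' @param W Symmetric connectivity/adjacency matrix (connected).
#' @param n_ensemble Number of random surrogate networks (default 100).
#' @param restarts Louvain restarts for the observed graph (default 10).
#' @param ensemble_restarts Louvain restarts per surrogate (default 2; the
#'   surrogate mean averages over the ensemble, so fewer restarts per
#'   surrogate suffice).
#' @param weighted Passed to [random_ensemble()].
#' @param seed Optional integer seed for the surrogate generation.
#' @return Named numeric vector with 9 entries: `pathlen`, `pathlen_norm`,
#'   `clust`, `clust_norm`, `smallworld`, `modularity`, `modularity_norm`,
#'   `strength`, `strength_norm`.
#' @export
graph_metrics <- function(W, n_ensemble = 100, restarts = 10,
                          ensemble_restarts = 2, weighted = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weighted)) weighted <- !all(W %in% c(0, 1))
  raw <- raw_graph_metrics(W, restarts)
  ne <- sum(W[upper.tri(W)] > 0)
  if (ne < 2) stop("graph has no swappable edge pairs")
  ens <- cpp_ensemble_metrics(W, as.integer(n_ensemble), weighted,
                              as.integer(ensemble_restarts), 10L)
  # rewired surrogates of sparse graphs may disconnect; average path length
  # over the connected surrogates only
  pl <- ens[, "pathlen"]
  ens_mean <- colMeans(ens)
  ens_mean["pathlen"] <- if (any(is.finite(pl))) mean(pl[is.finite(pl)])
  else NA_real_
  norm <- raw / ens_mean
  # degenerate ratios: 0/0 (e.g. a triangle-free graph whose surrogates are
  # also triangle-free) counts as indistinguishable from the ensemble
  zz <- !is.na(ens_mean) & ens_mean == 0 & raw == 0
  norm[zz] <- 1
  norm[!is.finite(norm)] <- NA_real_
  smallworld <- if (is.na(norm[["clust"]]) || is.na(norm[["pathlen"]]) ||
                    norm[["pathlen"]] == 0) NA_real_
  else norm[["clust"]] / norm[["pathlen"]]
  out <- c(pathlen = raw[["pathlen"]],
           pathlen_norm = norm[["pathlen"]],
           clust = raw[["clust"]],
           clust_norm = norm[["clust"]],
           smallworld = smallworld,
           modularity = raw[["modularity"]],
           modularity_norm = norm[["modularity"]],
           strength = raw[["strength"]],
           strength_norm = norm[["strength"]])
  out
}

#' Names of the 9 per-band graph metrics
#'
#' The five named network properties (path length, clustering coefficient,
#' small-worldness, modularity, node strength) plus the random-network
#' normalized variants of path length, clustering, modularity and strength
#' (small-worldness is itself a ratio of normalized quantities). Declared in
#' one place so the expansion can be revised centrally.
#'
#' @return Character vector of length 9.
#' @export
graph_metric_names <- function() {
  c("pathlen", "pathlen_norm", "clust", "clust_norm", "smallworld",
    "modularity", "modularity_norm", "strength", "strength_norm")
}

# modularity of a given membership (used as an oracle hook in tests and by
# the Louvain cross-checks)
modularity_value <- function(W, membership) {
  A <- W
  diag(A) <- 0
  two_m <- sum(A)
  if (two_m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / two_m - (sum(k[idx]) / two_m)^2
  }
  q
}
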