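star_matrix <- function(n = 19) {
  # hub weights dominate; all other pairs weak
  W <- matrix(runif(n * n, 0.01, 0.1), n, n)
  W[1, ] <- W[, 1] <- runif(n, 0.8, 1)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

test_that("spanning threshold finds the minimal connecting density", {
  set.seed(31)
  W <- star_matrix()
  expect_equal(spanning_threshold(W), 18 / 171)

  # complete graph of equal weights: first 18 edges in tie order connect
  expect_equal(spanning_threshold(matrix(1, 19, 19) - diag(19)), 18 / 171)

  # two heavy cliques bridged by a weak edge need more than a tree's density
  W2 <- matrix(0.01, 19, 19)
  W2[1:10, 1:10] <- runif(100, 0.8, 1)
  W2[11:19, 11:19] <- runif(81, 0.8, 1)
  W2 <- (W2 + t(W2)) / 2
  W2[1, 11] <- W2[11, 1] <- 0.5   # the strongest bridge
  diag(W2) <- 0
  expect_gt(spanning_threshold(W2), 18 / 171)

  Wz <- star_matrix()
  Wz[3, ] <- Wz[, 3] <- 0
  expect_error(spanning_threshold(Wz), "all-zero row")
})

test_that("binarization keeps the top-density edges deterministically", {
  set.seed(32)
  W <- star_matrix()
  B <- binarize(W, 1)
  expect_true(all(B[upper.tri(B)] == 1))

  Bs <- binarize(W, 18 / 171)
  expect_equal(sum(Bs[upper.tri(Bs)]), 18)
  expect_true(all(Bs[1, -1] == 1))          # exactly the star edges

  for (d in c(0.1, 0.33, 0.7)) {
    Bd <- binarize(W, d)
    expect_equal(sum(Bd[upper.tri(Bd)]), ceiling(d * 171))
    expect_equal(Bd, t(Bd))
  }

  # monotone nesting of edge sets in density
  B1 <- binarize(W, 0.2)
  B2 <- binarize(W, 0.5)
  expect_true(all(B2[B1 == 1] == 1))

  expect_error(binarize(W, 0), "density")
})

test_that("random surrogates preserve degrees; complete graphs are immovable", {
  set.seed(33)
  A <- (matrix(runif(361), 19) > 0.6) * 1
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  ens <- random_ensemble(A, n = 20, seed = 34)
  expect_length(ens, 20)
  for (R in ens) {
    expect_equal(rowSums(R), rowSums(A))
    expect_equal(R, t(R))
  }
  expect_true(any(vapply(ens, function(R) any(R != A), TRUE)))

  K <- matrix(1, 10, 10) - diag(10)
  for (R in random_ensemble(K, n = 5, seed = 35, weighted = FALSE)) {
    expect_equal(R, K)
  }

  # weighted surrogates permute the original weights over rewired edges
  set.seed(36)
  Wt <- star_matrix(10)
  for (R in random_ensemble(Wt, n = 5, seed = 37)) {
    expect_equal(sort(R[upper.tri(R)]), sort(Wt[upper.tri(Wt)]))
    expect_equal(rowSums(R > 0), rowSums(Wt > 0))
  }

  # a ring lattice loses clustering under degree-preserving rewiring
  ring <- matrix(0, 19, 19)
  for (i in 1:19) for (s in 1:2) {
    j <- ((i + s - 1) %% 19) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ens_r <- random_ensemble(ring, n = 30, seed = 38, weighted = FALSE)
  mean_cl <- mean(vapply(ens_r, eegpain:::cpp_clustering, 0))
  expect_lt(mean_cl, eegpain:::cpp_clustering(ring))
})

test_that("graph metrics match brute-force oracles on small random graphs", {
  set.seed(40)
  for (rep in seq_len(8)) {
    n <- sample(6:10, 1)
    W <- random_connected_graph(n, weighted = rep %% 2 == 0)
    m <- eegpain:::raw_graph_metrics(W, restarts = 20)
    expect_equal(m[["pathlen"]], brute_pathlength(W), tolerance = 1e-10)
    expect_equal(m[["clust"]], brute_clustering(W), tolerance = 1e-10)
    expect_equal(m[["strength"]], mean(rowSums(W)), tolerance = 1e-10)
    if (n <= 8) {
      expect_equal(m[["modularity"]], brute_max_modularity(W),
                   tolerance = 1e-9)
    }
  }
})

test_that("modularity of two bridged cliques equals the exhaustive bipartition maximum", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  diag(W) <- 0
  W[5, 6] <- W[6, 5] <- 1
  set.seed(41)
  lv <- eegpain:::cpp_louvain(W, 20)
  # exhaustive search over all 2^10 bipartitions
  best <- max(vapply(0:(2^10 - 1), function(mask) {
    memb <- as.integer(intToBits(mask))[1:10]
    eegpain:::modularity_value(W, memb)
  }, 0))
  expect_equal(lv$modularity, best, tolerance = 1e-10)
  # the optimum is the two-clique split
  expect_length(unique(lv$membership[1:5]), 1)
  expect_length(unique(lv$membership[6:10]), 1)
  expect_false(lv$membership[1] == lv$membership[10])
})

test_that("normalized metrics against an ensemble of itself equal one; complete graph anchors", {
  K <- matrix(1, 19, 19) - diag(19)
  g <- graph_metrics(K, n_ensemble = 10, seed = 42, weighted = FALSE)
  expect_equal(g[["clust"]], 1)
  expect_equal(g[["pathlen"]], 1)
  expect_equal(g[["strength"]], 18)
  # complete graph cannot be rewired: every normalized metric is exactly 1
  expect_equal(g[["pathlen_norm"]], 1)
  expect_equal(g[["clust_norm"]], 1)
  expect_equal(g[["smallworld"]], 1)
  expect_equal(g[["strength_norm"]], 1)

  expect_error(graph_metrics(diag(0, 19), n_ensemble = 5), "disconnected")
  one_edge <- matrix(c(0, 1, 1, 0), 2)
  expect_error(graph_metrics(one_edge, n_ensemble = 5), "swappable")
})

test_that("a rewired ring lattice shows small-world organization", {
  set.seed(43)
  hits <- replicate(7, {
    ring <- matrix(0, 19, 19)
    for (i in 1:19) for (s in 1:2) {
      j <- ((i + s - 1) %% 19) + 1
      ring[i, j] <- ring[j, i] <- 1
    }
    # rewire ~10% of edges
    edges <- which(upper.tri(ring) & ring == 1, arr.ind = TRUE)
    for (e in sample(nrow(edges), 4)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      cand <- which(ring[i, ] == 0 & seq_len(19) != i)
      k <- sample(cand, 1)
      ring[i, j] <- ring[j, i] <- 0
      ring[i, k] <- ring[k, i] <- 1
    }
    if (!is.finite(eegpain:::cpp_pathlength(ring))) return(NA)
    g <- graph_metrics(ring, n_ensemble = 20, weighted = FALSE)
    g[["smallworld"]]
  })
  expect_gt(mean(hits > 1, na.rm = TRUE), 0.5)
})

test_that("the assembled feature vector has the printed block structure", {
  nm <- feature_names()
  expect_length(nm, 380)
  info <- feature_info(nm)
  counts <- table(info$class)[feature_classes()]
  expect_equal(unname(c(counts)), c(76, 4, 76, 76, 76, 36, 36))

  # dropping the movement-affected classes leaves 192 features
  retained <- info$name[info$class %in% c("peakfreq", "pe", "dpli",
                                          "bgraph")]
  expect_length(retained, 192)

  # assembly demands complete, correctly ordered families
  fake <- function(names) setNames(seq_along(names), names)
  blocks <- split(info$name, info$class)[feature_classes()]
  v <- assemble_feature_vector(fake(blocks$power), fake(blocks$peakfreq),
                               fake(blocks$pe), fake(blocks$wpli),
                               fake(blocks$dpli), fake(blocks$bgraph),
                               fake(blocks$wgraph))
  expect_length(v, 380)
  expect_identical(names(v), nm)
  expect_error(
    assemble_feature_vector(fake(blocks$power), fake(blocks$peakfreq),
                            fake(blocks$pe), fake(blocks$wpli),
                            fake(blocks$dpli), fake(blocks$bgraph),
                            numeric(0)),
    "incomplete")
})
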