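# Shared fixtures and independent oracles for the test suite. Expensive
# cohorts are built once per run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixture_env[[key]] <- val
  val
}

fs_default <- 300

sine_epoch <- function(freq, n = 3000, fs = fs_default, nch = 1, amp = 1,
                       phase = 0) {
  t <- seq_len(n) / fs
  matrix(rep(amp * sin(2 * pi * freq * t + phase), nch), nrow = nch,
         byrow = TRUE)
}

# a tiny clean recording with controllable duration
toy_recording <- function(duration_s = 20, seed = 1, nch = 19,
                          fs = fs_default) {
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  data <- t(sapply(seq_len(nch), function(c) {
    sin(2 * pi * (5 + c / 10) * t) + 0.5 * rnorm(n)
  }))
  eeg_recording(data, eeg_montage(), subject_id = "t_01",
                group = "healthy", condition = "baseline")
}

# small clean cohort with a moderate condition effect, full extraction;
# reused by feature-structure, pipeline and acceptance tests
demo_features <- function() {
  memo("demo_features", function() {
    cfg <- cohort_config(n_subjects_per_group = 2,
                         epochs_per_condition = c(baseline = 2, cpt = 2),
                         effect = demo_effect(), seed = 301)
    recs <- generate_cohort(cfg)
    extract_features(recs, extraction_settings(n_ensemble = 20, seed = 301))
  })
}

band_by_name_test <- function(bands, name) bands[bands$name == name, ]

# mover-contaminated cohort for the movement screen, full 380 extraction
screen_features <- function() {
  memo("screen_features", function() {
    cfg <- cohort_config(n_subjects_per_group = 5, movement_fraction = 0.6,
                         epochs_per_condition = c(baseline = 6, cpt = 1),
                         seed = 23)
    recs <- generate_cohort(cfg)
    extract_features(recs, extraction_settings(n_ensemble = 20, seed = 23))
  })
}

## ---- independent oracles ----------------------------------------------

# brute-force ordinal pattern counting via order() on every window
brute_pattern_counts <- function(series, m, tau) {
  n_win <- length(series) - (m - 1) * tau
  pats <- vapply(seq_len(n_win), function(t) {
    w <- series[t + (0:(m - 1)) * tau]
    # ranks under temporal tie-break = order of stable sort
    paste(rank(w, ties.method = "first"), collapse = "")
  }, "")
  table(pats)
}

brute_pe <- function(series, m, tau) {
  counts <- as.numeric(brute_pattern_counts(series, m, tau))
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(factorial(m))
}

# all-pairs shortest paths by explicit Dijkstra (edge length 1/weight)
brute_pathlength <- function(W) {
  n <- nrow(W)
  total <- 0
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    visited <- rep(FALSE, n)
    for (step in seq_len(n)) {
      u <- which.min(ifelse(visited, Inf, dist))
      if (!is.finite(dist[u])) break
      visited[u] <- TRUE
      for (v in seq_len(n)) {
        if (W[u, v] > 0 && !visited[v]) {
          alt <- dist[u] + 1 / W[u, v]
          if (alt < dist[v]) dist[v] <- alt
        }
      }
    }
    if (any(!is.finite(dist[-src]))) return(Inf)
    total <- total + sum(dist[-src])
  }
  total / (n * (n - 1))
}

# explicit triangle-weight clustering (geometric mean form, weights scaled
# by the maximum), degree < 2 contributes 0
brute_clustering <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W[row(W) != col(W)])
  diag(Wn) <- 0
  cs <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(Wn[i, ] > 0)
    if (k < 2) next
    t <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j != i && l != i && l != j) {
          t <- t + (Wn[i, j] * Wn[j, l] * Wn[l, i])^(1 / 3)
        }
      }
    }
    cs[i] <- t / (k * (k - 1))
  }
  mean(cs)
}

# all set partitions of 1:n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0L)
  out
}

# exhaustive maximum modularity over every partition (n <= 8)
brute_max_modularity <- function(W) {
  parts <- all_partitions(nrow(W))
  max(vapply(parts, function(p) eegpain:::modularity_value(W, p), 0))
}

random_connected_graph <- function(n, weighted = TRUE, p_edge = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    vals <- ifelse(stats::runif(sum(up)) < p_edge,
                   if (weighted) stats::runif(sum(up), 0.1, 1) else 1, 0)
    A[up] <- vals
    A <- A + t(A)
    if (is.finite(brute_pathlength(A))) return(A)
  }
}
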