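#' Permutation-entropy parameters
#'
#' @param m Embedding dimension (number of samples per ordinal motif),
#'   default 5.
#' @param tau Time lag in samples between motif elements, default 4.
#' @return An object of class `pe_spec`.
#' @export
pe_spec <- function(m = 5, tau = 4) {
  if (m < 2) stop("embedding dimension m must be >= 2")
  if (m > 8) stop("embedding dimension m > 8 not supported")
  if (tau < 1) stop("time lag tau must be >= 1")
  structure(list(m = as.integer(m), tau = as.integer(tau)), class = "pe_spec")
}

# all permutations of 1:m in lexicographic order (memoized: needed for
# every epoch x channel x band)
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(m) {
  key <- as.character(m)
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (m == 1) list(1L) else {
    acc <- list()
    for (first in seq_len(m)) {
      rest <- setdiff(seq_len(m), first)
      for (sub in all_permutations(m - 1)) {
        acc[[length(acc) + 1L]] <- c(first, rest[sub])
      }
    }
    acc
  }
  .perm_cache[[key]] <- out
  out
}

# per-m lookup: base-m encoding of each permutation's rank vector, used to
# fold the window-id tabulation into motif counts
.motif_cache <- new.env(parent = emptyenv())

motif_ids <- function(m) {
  key <- as.character(m)
  hit <- .motif_cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- all_permutations(m)
  ids <- vapply(perms, function(rk) {
    sum((rk - 1L) * m^(seq_len(m) - 1L)) + 1L
  }, 0)
  names(ids) <- vapply(perms, paste, "", collapse = "")
  .motif_cache[[key]] <- ids
  ids
}

#' Ordinal pattern (motif) counts of a time series
#'
#' Each embedding window `(x_t, x_(t+tau), ..., x_(t+(m-1)tau))` is mapped to
#' the permutation of time indices that sorts it ascending; ties are broken
#' by temporal order (stable sort, the Bandt-Pompe convention). Counts are
#' returned over all `m!` motifs, named by the rank sequence of the window
#' elements (e.g. `"12"` = rising pair, `"21"` = falling pair).
#'
#' @param series Numeric vector, length at least `(m-1)*tau + 1`.
#' @param spec A [pe_spec()].
#' @return Named integer vector of length `m!` summing to
#'   `length(series) - (m-1)*tau`.
#' @export
ordinal_pattern_counts <- function(series, spec = pe_spec()) {
  m <- spec$m
  tau <- spec$tau
  n <- length(series)
  n_win <- n - (m - 1L) * tau
  if (n_win < 1) stop("series too short for (m-1)*tau + 1 samples")
  E <- matrix(0, m, n_win)
  for (k in seq_len(m)) {
    E[k, ] <- series[((k - 1L) * tau + 1L):((k - 1L) * tau + n_win)]
  }
  # rank of element k inside its window under stable (temporal) tie-break
  R <- matrix(1L, m, n_win)
  for (k in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j == k) next
      if (j < k) R[k, ] <- R[k, ] + (E[j, ] <= E[k, ])
      else       R[k, ] <- R[k, ] + (E[j, ] <  E[k, ])
    }
  }
  # encode rank vectors in base m
  id <- rep(0, n_win)
  for (k in seq_len(m)) id <- id + (R[k, ] - 1L) * m^(k - 1L)
  tab <- tabulate(id + 1L, nbins = m^m)
  ids <- motif_ids(m)
  counts <- tab[ids]
  names(counts) <- names(ids)
  counts
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-motif relative frequencies, normalized by
#' `log(m!)` so the result lies in \[0, 1\]: 0 for a strictly monotone
#' (single-motif) series, 1 when all motifs are equally frequent. Values near
#' 1 indicate an irregular, high-frequency-dominated signal.
#'
#' @inheritParams ordinal_pattern_counts
#' @return Normalized entropy in \[0, 1\].
#' @export
permutation_entropy <- function(series, spec = pe_spec()) {
  counts <- ordinal_pattern_counts(series, spec)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(factorial(spec$m))
}

# permutation entropy of every row of a channels x samples matrix in one
# vectorized pass (the feature extractor computes 76 of these per epoch)
pe_channels <- function(x, spec = pe_spec()) {
  m <- spec$m
  tau <- spec$tau
  nch <- nrow(x)
  n <- ncol(x)
  n_win <- n - (m - 1L) * tau
  if (n_win < 1) stop("series too short for (m-1)*tau + 1 samples")
  E <- lapply(seq_len(m), function(k) {
    x[, ((k - 1L) * tau + 1L):((k - 1L) * tau + n_win), drop = FALSE]
  })
  R <- lapply(seq_len(m), function(k) {
    r <- matrix(1L, nch, n_win)
    for (j in seq_len(m)) {
      if (j == k) next
      r <- r + if (j < k) (E[[j]] <= E[[k]]) else (E[[j]] < E[[k]])
    }
    r
  })
  id <- matrix(0, nch, n_win)
  for (k in seq_len(m)) id <- id + (R[[k]] - 1L) * m^(k - 1L)
  # offset ids per channel so one tabulate covers all rows
  id <- id + (seq_len(nch) - 1L) * m^m
  tab <- tabulate(as.vector(id) + 1L, nbins = nch * m^m)
  log_mfact <- log(factorial(m))
  vapply(seq_len(nch), function(c) {
    counts <- tab[((c - 1L) * m^m + 1L):(c * m^m)]
    p <- counts[counts > 0] / n_win
    -sum(p * log(p)) / log_mfact
  }, 0)
}
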