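#' Analytic signal via the Hilbert transform
#'
#' @param x Numeric vector (one channel of band-filtered signal).
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) stop("zero-length input")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal, radians in `(-pi, pi]`. Meaningful only for
#' narrowband input.
#'
#' @inheritParams analytic_signal
#' @return Numeric vector of phases.
#' @export
analytic_phase <- function(x) {
  Arg(analytic_signal(x))
}

# analytic signals for all channels, with the first/last `trim` fraction of
# samples dropped to suppress Hilbert end effects
analytic_matrix <- function(x, trim = 0.05) {
  n <- ncol(x)
  keep <- (floor(trim * n) + 1):(n - floor(trim * n))
  A <- matrix(0i, nrow(x), length(keep))
  for (c in seq_len(nrow(x))) {
    A[c, ] <- analytic_signal(x[c, ])[keep]
  }
  A
}

#' Weighted phase lag index (wPLI) matrix
#'
#' For each channel pair, with `z_t = a_i(t) * Conj(a_j(t))` the analytic
#' cross-signal, `wPLI = |mean(Im z)| / mean(|Im z|)`. Phase-difference signs
#' are weighted by the magnitude of the imaginary cross-spectrum, making the
#' index insensitive to volume-conducted (zero-lag) coupling. The degenerate
#' 0/0 case (identical channels, perfectly real cross-spectrum) is defined
#' as 0: no evidence of lagged interaction.
#'
#' @param x Channels x samples matrix of band-filtered signal (or an
#'   `eeg_epoch`).
#' @param trim Fraction of samples discarded at each edge before phase
#'   statistics (Hilbert end effects), default 0.05.
#' @return Symmetric matrix in \[0, 1\] with zero diagonal; attribute
#'   `kind = "wpli"`.
#' @export
wpli <- function(x, trim = 0.05) {
  if (is.list(x)) x <- x$data
  if (nrow(x) < 2) stop("need at least 2 channels")
  phase_lag_indices(analytic_matrix(x, trim))$wpli
}

# both phase-lag indices from one analytic-signal matrix (the imaginary
# cross-terms are shared, and feature extraction needs both per band);
# the pairwise reduction runs in compiled code
phase_lag_indices <- function(A) {
  out <- cpp_phase_lag(Re(A), Im(A))
  attr(out$wpli, "kind") <- "wpli"
  attr(out$dpli, "kind") <- "dpli"
  out
}

#' Directed phase lag index (dPLI) matrix
#'
#' `dPLI(i, j)` is the fraction of samples at which channel `i`'s phase leads
#' channel `j`'s (wrapped phase difference positive), with simultaneous
#' phases counted 1/2. Values above 0.5 mean `i` leads `j`;
#' `dPLI(i, j) + dPLI(j, i) = 1` and the diagonal is 0.5.
#'
#' @inheritParams wpli
#' @return Matrix in \[0, 1\] with attribute `kind = "dpli"`.
#' @export
dpli <- function(x, trim = 0.05) {
  if (is.list(x)) x <- x$data
  if (nrow(x) < 2) stop("need at least 2 channels")
  # sign of Im(a_i conj(a_j)) = sign of the wrapped phase difference
  phase_lag_indices(analytic_matrix(x, trim))$dpli
}

#' Per-channel mean connectivity (row means excluding the diagonal)
#'
#' @param m A connectivity matrix ([wpli()] or [dpli()] output).
#' @return Numeric vector of row means, one per channel.
#' @export
connectivity_row_means <- function(m) {
  n <- nrow(m)
  (rowSums(m) - diag(m)) / (n - 1)
}
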