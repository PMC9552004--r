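# cache Slepian tapers per (n, nw, k): recomputing them for every epoch
# would dominate the spectral stage
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers; must satisfy `k <= 2*nw - 1`.
#' @return An `n x k` matrix of unit-norm tapers, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  tap <- cpp_dpss(as.integer(n), nw, as.integer(k))
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density of an epoch
#'
#' Averages `K` Slepian eigenspectra per channel. One-sided density scaled so
#' that the integral over frequency approximates the signal variance.
#' The frequency grid has a resolution of at most `df` Hz (zero-padding where
#' the epoch length alone would be coarser; a 10-s epoch at 300 Hz natively
#' yields the default 0.1 Hz grid).
#'
#' @param epoch An `eeg_epoch`, `eeg_recording`, or channels x samples matrix.
#' @param k Number of tapers (default 3).
#' @param nw Time-bandwidth product (default 2).
#' @param fs Sampling rate (taken from the montage when available).
#' @param df Maximum frequency-grid spacing in Hz.
#' @return Object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `power` (channels x frequencies, density in uV^2/Hz), `k`, `nw`.
#' @export
multitaper_psd <- function(epoch, k = 3, nw = 2, fs = NULL, df = 0.1) {
  x <- if (is.list(epoch)) epoch$data else epoch
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(fs)) {
    if (is.list(epoch)) fs <- epoch$montage$sampling_rate
    else stop("fs required for matrix input")
  }
  if (k > 2 * nw - 1 + 1e-9) stop("Slepian constraint requires k <= 2*nw - 1")
  n <- ncol(x)
  nfft <- max(n, ceiling(fs / df))
  tapers <- dpss_tapers(n, nw, k)
  nfreq <- floor(nfft / 2) + 1
  freqs <- (seq_len(nfreq) - 1) * fs / nfft
  pow <- matrix(0, nrow(x), nfreq)
  for (ch in seq_len(nrow(x))) {
    s <- numeric(nfreq)
    for (j in seq_len(k)) {
      xt <- c(x[ch, ] * tapers[, j], numeric(nfft - n))
      X <- stats::fft(xt)[seq_len(nfreq)]
      s <- s + (Mod(X)^2) / fs
    }
    s <- s / k
    # one-sided: double everything except DC (and Nyquist when on the grid)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[nfreq] <- 1
    pow[ch, ] <- s * dbl
  }
  structure(list(frequencies = freqs, power = pow, k = k, nw = nw, fs = fs),
            class = "power_spectrum")
}

#' Band power per channel
#'
#' Trapezoidal integral of the power spectral density over a band's closed
#' frequency interval. Shared band edges contribute half to each side, so
#' adjacent bands tile the total power exactly.
#'
#' @param spectrum A `power_spectrum`.
#' @param band One-row data frame with `low`, `high` (as in
#'   [default_bands()]), or a numeric `c(low, high)`.
#' @return Named numeric vector: integrated power per channel (uV^2).
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  edges <- if (is.data.frame(band)) c(band$low, band$high) else band
  f <- spectrum$frequencies
  if (edges[1] < min(f) || edges[2] > max(f)) stop("band outside spectrum grid")
  idx <- which(f >= edges[1] & f <= edges[2])
  if (length(idx) < 2) stop("band contains fewer than two grid points")
  apply(spectrum$power, 1, function(p) {
    sum(diff(f[idx]) * (p[idx[-length(idx)]] + p[idx[-1]]) / 2)
  })
}

#' Peak frequency of the channel-averaged spectrum within a band
#'
#' The spectrum is first averaged over channels (arithmetic mean), then the
#' frequency with the largest power inside the band's closed interval is
#' returned. Ties resolve to the lowest frequency.
#'
#' @inheritParams band_power
#' @return Peak frequency in Hz (single value).
#' @export
peak_frequency <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  edges <- if (is.data.frame(band)) c(band$low, band$high) else band
  f <- spectrum$frequencies
  if (edges[1] < min(f) || edges[2] > max(f)) stop("band outside spectrum grid")
  idx <- which(f >= edges[1] & f <= edges[2])
  avg <- colMeans(spectrum$power[, idx, drop = FALSE])
  f[idx[which.max(avg)]]
}
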