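#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' (zero phase, so phase-based connectivity features are not distorted).
#' For pass-bands with a very low lower edge relative to the sampling rate
#' (broadband 0.1-50 Hz at 300 Hz) the filter is applied as a high-pass /
#' low-pass cascade, which is numerically better conditioned than a single
#' narrow-normalized band-pass transfer function.
#'
#' @param rec An `eeg_recording`, or a channels x samples matrix.
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Filter order (default 4).
#' @param fs Sampling rate; taken from the montage when `rec` is a recording.
#' @return Filtered object of the same type as `rec`.
#' @export
bandpass <- function(rec, low, high, order = 4, fs = NULL) {
  is_rec <- inherits(rec, "eeg_recording")
  x <- if (is_rec) rec$data else rec
  if (is_rec) fs <- rec$montage$sampling_rate
  if (is.null(fs)) stop("fs is required for matrix input")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2")
  }
  y <- filter_matrix(x, low, high, order, fs)
  if (is_rec) { rec$data <- y; rec } else y
}

filter_matrix <- function(x, low, high, order, fs) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nyq <- fs / 2
  if (low / nyq < 0.01) {
    hp <- signal::butter(order, low / nyq, type = "high")
    lp <- signal::butter(order, high / nyq, type = "low")
    t(filtfilt_cols(lp$b, lp$a, filtfilt_cols(hp$b, hp$a, t(x))))
  } else {
    bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
    t(filtfilt_cols(bp$b, bp$a, t(x)))
  }
}

# single-direction IIR with zero initial conditions, column-wise
iir_cols <- function(b, a, X) {
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  ma <- stats::filter(Xp, b / a[1], method = "convolution", sides = 1)
  ma <- ma[-seq_len(nb - 1), , drop = FALSE]
  as.matrix(stats::filter(ma, -a[-1] / a[1], method = "recursive"))
}

# forward-backward (zero-phase) filtering of every column of X; matches
# signal::filtfilt exactly (zero padding of twice the filter length) but
# filters all channels in two passes instead of two per channel
filtfilt_cols <- function(b, a, X) {
  n <- nrow(X)
  pad <- 2 * max(length(a), length(b))
  Y <- iir_cols(b, a, rbind(X, matrix(0, pad, ncol(X))))
  Y <- iir_cols(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the mean of the named reference channels from every channel.
#' When `reference` is empty (the simulated montage carries no A1/A2
#' electrodes) the recording is returned unchanged, mirroring a "none"
#' fallback.
#'
#' @param rec An `eeg_recording`.
#' @param reference Character vector of reference channel labels (subset of
#'   the montage), or `character()` for no re-referencing.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, reference = character()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(reference) == 0) return(rec)
  idx <- match(reference, rec$montage$channel_labels)
  if (anyNA(idx)) stop("reference channels not in montage: ",
                       paste(reference[is.na(idx)], collapse = ", "))
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)
  rec
}

#' Detect bad channels by robust amplitude z-score
#'
#' Computes each channel's RMS amplitude and flags channels whose robust
#' z-score (median/MAD) exceeds `z_thresh` in absolute value. A deterministic
#' stand-in for manual channel inspection: catches both runaway (high-RMS)
#' and dead (flat) channels.
#'
#' @param rec An `eeg_recording` or channels x samples matrix.
#' @param z_thresh Absolute robust z-score threshold (default 5).
#' @return Character vector of flagged channel labels (or indices for a bare
#'   matrix).
#' @export
detect_bad_channels <- function(rec, z_thresh = 5) {
  is_rec <- inherits(rec, "eeg_recording")
  x <- if (is_rec) rec$data else rec
  if (nrow(x) < 2) stop("need at least 2 channels")
  rms <- sqrt(rowMeans(x^2))
  med <- stats::median(rms)
  scale <- stats::mad(rms)
  if (scale == 0) scale <- stats::sd(rms)
  if (is.na(scale) || scale == 0) return(if (is_rec) character() else integer())
  z <- (rms - med) / scale
  bad <- which(abs(z) > z_thresh)
  if (length(bad) == nrow(x)) stop("all channels flagged bad; recording unusable")
  if (is_rec) rec$montage$channel_labels[bad] else bad
}

#' Segment a recording into non-overlapping 10-second epochs
#'
#' @param rec An `eeg_recording`.
#' @param length_s Epoch length in seconds (default 10).
#' @param bad_channels Labels carried into each epoch's `bad_channels` field.
#' @return List of `eeg_epoch` objects; the trailing remainder shorter than
#'   one epoch is discarded.
#' @export
segment_epochs <- function(rec, length_s = 10, bad_channels = character()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$montage$sampling_rate
  len <- as.integer(length_s * fs)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1) stop("recording shorter than one epoch")
  lapply(seq_len(n_ep), function(i) {
    seg <- rec$data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
    structure(list(data = seg, montage = rec$montage,
                   subject_id = rec$subject_id, group = rec$group,
                   condition = rec$condition, mover = rec$mover,
                   epoch_index = i, bad_channels = bad_channels),
              class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat("<eeg_epoch> subject ", x$subject_id, " [", x$condition, "] #",
      x$epoch_index, ", ", nrow(x$data), " ch x ", ncol(x$data),
      " samples\n", sep = "")
  invisible(x)
}

#' Mean-impute missing entries of a feature matrix
#'
#' Missing cells (features lost with removed bad channels) are replaced by
#' the column mean over observed entries; observed cells are untouched.
#'
#' @param table Numeric matrix or data frame; `NA` marks missing.
#' @return Object of the same type with no missing entries.
#' @export
impute_missing_features <- function(table) {
  is_df <- is.data.frame(table)
  m <- as.matrix(table)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) stop("column ", j, " is fully missing; cannot impute")
    if (any(miss)) m[miss, j] <- mean(m[!miss, j])
  }
  if (is_df) {
    out <- as.data.frame(m)
    names(out) <- names(table)
    out
  } else m
}
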