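#' Standard 10-20 channel labels
#'
#' The 19 scalp electrodes of the international 10-20 system in the fixed
#' order used throughout the package (anterior to posterior, left to right).
#'
#' @return Character vector of 19 channel labels.
#' @export
standard_1020_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' EEG montage specification
#'
#' @param channel_labels Ordered character vector of unique channel labels.
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the highest
#'   analysis band edge (30 Hz).
#' @return An object of class `eeg_montage`.
#' @export
eeg_montage <- function(channel_labels = standard_1020_labels(),
                        sampling_rate = 300) {
  stopifnot(is.character(channel_labels), length(channel_labels) >= 2,
            !anyDuplicated(channel_labels))
  if (sampling_rate <= 2 * 30) {
    stop("sampling_rate must exceed twice the highest band edge (30 Hz)")
  }
  structure(list(channel_labels = channel_labels,
                 sampling_rate = sampling_rate),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_labels), " channels @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz).
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low  = c(1, 4, 8, 13),
             high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

band_by_name <- function(bands, name) {
  i <- match(name, bands$name)
  if (is.na(i)) stop("unknown band: ", name)
  bands[i, , drop = FALSE]
}

#' Construct an EEG recording object
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param montage An [eeg_montage()].
#' @param subject_id Subject identifier.
#' @param group `"healthy"` or `"pain"`.
#' @param condition `"baseline"` or `"cpt"`.
#' @param mover Logical; did this subject make voluntary movements at baseline.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, montage, subject_id, group, condition,
                          mover = FALSE) {
  stopifnot(is.matrix(data), nrow(data) == length(montage$channel_labels),
            all(is.finite(data)))
  group <- match.arg(group, c("healthy", "pain"))
  condition <- match.arg(condition, c("baseline", "cpt"))
  structure(list(data = data, montage = montage, subject_id = subject_id,
                 group = group, condition = condition, mover = isTRUE(mover)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject ", x$subject_id, " [", x$group, "/",
      x$condition, if (x$mover) ", mover" else "", "] ",
      nrow(x$data), " ch x ", ncol(x$data), " samples (",
      round(ncol(x$data) / x$montage$sampling_rate, 1), " s)\n", sep = "")
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$montage$sampling_rate
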