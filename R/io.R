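#' Write a feature table to CSV
#'
#' Long-header CSV: key columns `subject,group,condition,mover,epoch`
#' followed by the feature columns; missing values are empty cells.
#'
#' @param table Feature table from [extract_features()].
#' @param path Output file path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file path.
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(subject = "character"))
  out$mover <- as.logical(out$mover)
  out
}

#' Write a recording as a CSV matrix with a JSON sidecar
#'
#' The signal is stored as a channels x samples CSV (one row per channel,
#' no header) next to a `.json` sidecar holding subject id, group,
#' condition, mover flag and montage.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  utils::write.table(rec$data, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               condition = rec$condition, mover = rec$mover,
               channel_labels = rec$montage$channel_labels,
               sampling_rate = rec$montage$sampling_rate)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#' @param prefix Path prefix used when writing.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(data) <- NULL
  eeg_recording(data,
                eeg_montage(meta$channel_labels, meta$sampling_rate),
                meta$subject_id, meta$group, meta$condition, meta$mover)
}

#' Write a cohort of recordings to a directory
#'
#' @param recordings List of `eeg_recording`s.
#' @param dir Output directory (created if absent).
#' @return Character vector of prefixes, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefixes <- vapply(recordings, function(r) {
    file.path(dir, paste(r$subject_id, r$condition, sep = "_"))
  }, "")
  for (i in seq_along(recordings)) {
    write_recording(recordings[[i]], prefixes[i])
  }
  invisible(prefixes)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `.csv`/`.json` recording pairs.
#' @return List of `eeg_recording`s.
#' @export
read_cohort <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(sub("\\.json$", "", sidecars), read_recording)
}

#' Write a screening result to JSON
#' @param screening A `screening_result` (or NULL for a no-screen run).
#' @param path Output path.
#' @export
write_screening_json <- function(screening, path) {
  payload <- if (is.null(screening)) {
    list(screened = FALSE, classes = NULL, retained = NULL)
  } else {
    list(screened = TRUE,
         threshold = attr(screening, "threshold"),
         classes = as.data.frame(screening),
         retained = attr(screening, "retained"))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}
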