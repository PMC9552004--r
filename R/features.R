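#' Extraction settings
#'
#' Bundles every tunable of the feature-extraction stage. Defaults follow the
#' analysis conventions used throughout the package: 4th-order zero-phase
#' Butterworth band filters, multitaper spectra with K = 3 tapers and
#' NW = 2, permutation entropy with embedding dimension 5 and lag 4, and
#' graph normalization against 100 degree-preserving random networks.
#'
#' @param bands Band definition table as from [default_bands()].
#' @param pe A [pe_spec()].
#' @param psd_k,psd_nw Multitaper taper count and time-bandwidth product.
#' @param broadband Pre-filter corner frequencies in Hz.
#' @param reference Reference channel labels for [rereference()] (empty =
#'   no re-referencing; the simulated montage carries no ear electrodes).
#' @param bad_channel_z Robust z threshold of [detect_bad_channels()].
#' @param trim Edge fraction discarded before phase statistics.
#' @param n_ensemble Random networks per graph normalization.
#' @param restarts Louvain restarts for observed graphs.
#' @param ensemble_restarts Louvain restarts per surrogate network.
#' @param seed Seed for the surrogate-network generator.
#' @param classes Feature classes to compute (default all 7); restricting to
#'   the classes a subset analysis needs skips the corresponding work.
#' @return An object of class `extraction_settings`.
#' @export
extraction_settings <- function(bands = default_bands(), pe = pe_spec(),
                                psd_k = 3, psd_nw = 2,
                                broadband = c(0.1, 50),
                                reference = character(),
                                bad_channel_z = 5, trim = 0.05,
                                n_ensemble = 100, restarts = 10,
                                ensemble_restarts = 2, seed = 1,
                                classes = feature_classes()) {
  classes <- match.arg(classes, feature_classes(), several.ok = TRUE)
  structure(list(bands = bands, pe = pe, psd_k = psd_k, psd_nw = psd_nw,
                 broadband = broadband, reference = reference,
                 bad_channel_z = bad_channel_z, trim = trim,
                 n_ensemble = n_ensemble, restarts = restarts,
                 ensemble_restarts = ensemble_restarts, seed = seed,
                 classes = classes),
            class = "extraction_settings")
}

#' Canonical names of the 380-entry feature vector
#'
#' 76 spectral power + 4 peak frequency + 76 permutation entropy + 76 wPLI +
#' 76 dPLI + 36 binary-graph + 36 weighted-graph features.
#'
#' @param montage An [eeg_montage()].
#' @param bands Band table.
#' @return Character vector of length 380.
#' @export
feature_names <- function(montage = eeg_montage(), bands = default_bands()) {
  ch <- montage$channel_labels
  bn <- bands$name
  per_chan <- function(prefix) {
    unlist(lapply(bn, function(b) paste(prefix, b, ch, sep = "_")))
  }
  c(per_chan("power"),
    paste("peakfreq", bn, sep = "_"),
    per_chan("pe"),
    per_chan("wpli"),
    per_chan("dpli"),
    unlist(lapply(bn, function(b) paste("bgraph", graph_metric_names(), b,
                                        sep = "_"))),
    unlist(lapply(bn, function(b) paste("wgraph", graph_metric_names(), b,
                                        sep = "_"))))
}

#' Feature metadata from feature names
#'
#' @param names Character vector of feature names as produced by
#'   [feature_names()].
#' @return Data frame with columns `name`, `class` (one of power, peakfreq,
#'   pe, wpli, dpli, bgraph, wgraph), `band`, and `channel` (`NA` for
#'   peak-frequency and graph features, which are not channel-resolved).
#' @export
feature_info <- function(names) {
  parts <- strsplit(names, "_")
  cls <- vapply(parts, `[`, "", 1)
  band <- ifelse(cls %in% c("bgraph", "wgraph"),
                 vapply(parts, function(p) p[length(p)], ""),
                 vapply(parts, `[`, "", 2))
  channel <- ifelse(cls %in% c("power", "pe", "wpli", "dpli"),
                    vapply(parts, function(p) p[3], ""), NA)
  data.frame(name = names, class = cls, band = band, channel = channel,
             stringsAsFactors = FALSE)
}

#' The 7 feature classes
#' @return Character vector.
#' @export
feature_classes <- function() {
  c("power", "peakfreq", "pe", "wpli", "dpli", "bgraph", "wgraph")
}

#' Assemble one epoch's families into the 380-entry feature vector
#'
#' @param power Named vector of 19 x 4 band powers (band-major).
#' @param peakfreq Named vector of 4 peak frequencies.
#' @param pe Named vector of 19 x 4 permutation entropies.
#' @param wpli_rm,dpli_rm Named vectors of 19 x 4 connectivity row means.
#' @param bgraph,wgraph Named vectors of 9 x 4 graph metrics.
#' @param montage,bands Used to validate the canonical name order.
#' @return Named numeric vector of length 380.
#' @export
assemble_feature_vector <- function(power, peakfreq, pe, wpli_rm, dpli_rm,
                                    bgraph, wgraph,
                                    montage = eeg_montage(),
                                    bands = default_bands()) {
  v <- c(power, peakfreq, pe, wpli_rm, dpli_rm, bgraph, wgraph)
  expected <- feature_names(montage, bands)
  if (length(v) != length(expected)) {
    stop("feature families incomplete: got ", length(v), " of ",
         length(expected), " features")
  }
  if (!identical(names(v), expected)) {
    stop("feature names do not match the canonical order")
  }
  v
}

# band-filter one epoch matrix into a list of per-band matrices
band_filtered <- function(x, fs, bands, order = 4) {
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    out[[b]] <- filter_matrix(x, bands$low[b], bands$high[b], order, fs)
  }
  out
}

# non-graph feature families + per-band wPLI/dPLI matrices for one epoch;
# `bf` holds the epoch's band-filtered segments (the band filter runs once
# over the continuous recording, not per epoch, to avoid per-epoch filter
# transients)
epoch_base_features <- function(epoch, bf, settings, bad_idx = integer()) {
  ch <- epoch$montage$channel_labels
  bands <- settings$bands
  cls <- settings$classes
  need_spec <- any(c("power", "peakfreq") %in% cls)
  need_wpli <- any(c("wpli", "bgraph", "wgraph") %in% cls)
  spec <- if (need_spec) {
    multitaper_psd(epoch, k = settings$psd_k, nw = settings$psd_nw)
  }

  power <- numeric(0); pe_v <- numeric(0)
  wpli_v <- numeric(0); dpli_v <- numeric(0)
  peak <- numeric(0)
  wpli_mats <- vector("list", nrow(bands))
  names(wpli_mats) <- bands$name
  for (b in seq_len(nrow(bands))) {
    bn <- bands$name[b]
    if ("power" %in% cls) {
      bp <- band_power(spec, bands[b, ])
      names(bp) <- paste("power", bn, ch, sep = "_")
      if (length(bad_idx)) bp[bad_idx] <- NA
      power <- c(power, bp)
    }
    if ("peakfreq" %in% cls) {
      pk <- peak_frequency(spec, bands[b, ])
      names(pk) <- paste("peakfreq", bn, sep = "_")
      peak <- c(peak, pk)
    }
    if ("pe" %in% cls) {
      pe_b <- pe_channels(bf[[b]], settings$pe)
      names(pe_b) <- paste("pe", bn, ch, sep = "_")
      if (length(bad_idx)) pe_b[bad_idx] <- NA
      pe_v <- c(pe_v, pe_b)
    }
    if (need_wpli || "dpli" %in% cls) {
      pli <- phase_lag_indices(analytic_matrix(bf[[b]], settings$trim))
      wpli_mats[[b]] <- pli$wpli
      if ("wpli" %in% cls) {
        w_rm <- connectivity_row_means(pli$wpli)
        names(w_rm) <- paste("wpli", bn, ch, sep = "_")
        if (length(bad_idx)) w_rm[bad_idx] <- NA
        wpli_v <- c(wpli_v, w_rm)
      }
      if ("dpli" %in% cls) {
        d_rm <- connectivity_row_means(pli$dpli)
        names(d_rm) <- paste("dpli", bn, ch, sep = "_")
        if (length(bad_idx)) d_rm[bad_idx] <- NA
        dpli_v <- c(dpli_v, d_rm)
      }
    }
  }
  list(power = power, peakfreq = peak, pe = pe_v, wpli = wpli_v,
       dpli = dpli_v, wpli_mats = wpli_mats)
}

# graph families for one epoch given its wPLI matrices and the participant's
# per-band binarization densities
epoch_graph_features <- function(wpli_mats, densities, settings) {
  bands <- names(wpli_mats)
  bg <- numeric(0); wg <- numeric(0)
  for (bn in bands) {
    W <- wpli_mats[[bn]]
    if ("bgraph" %in% settings$classes) {
      B <- binarize(W, densities[[bn]])
      # a single epoch thresholded at the participant density may
      # disconnect; raise to the epoch's own spanning density in that case
      if (!is.finite(cpp_pathlength(B))) {
        B <- binarize(W, spanning_threshold(W))
      }
      gb <- graph_metrics(B, n_ensemble = settings$n_ensemble,
                          restarts = settings$restarts,
                          ensemble_restarts = settings$ensemble_restarts,
                          weighted = FALSE)
      names(gb) <- paste("bgraph", graph_metric_names(), bn, sep = "_")
      bg <- c(bg, gb)
    }
    if ("wgraph" %in% settings$classes) {
      gw <- graph_metrics(W, n_ensemble = settings$n_ensemble,
                          restarts = settings$restarts,
                          ensemble_restarts = settings$ensemble_restarts,
                          weighted = TRUE)
      names(gw) <- paste("wgraph", graph_metric_names(), bn, sep = "_")
      wg <- c(wg, gw)
    }
  }
  list(bgraph = bg, wgraph = wg)
}

#' Extract the full feature table from a cohort of recordings
#'
#' Runs the complete preprocessing and feature pipeline: broadband zero-phase
#' filtering, optional re-referencing, robust bad-channel detection,
#' segmentation into 10-s epochs, band-resolved feature computation
#' (spectral power, peak frequency, permutation entropy, wPLI/dPLI row
#' means) and graph-theory metrics of the per-epoch wPLI matrices. Each
#' participant's binary-graph threshold per band is the minimally spanning
#' density of their mean baseline wPLI matrix, applied to all of that
#' participant's epochs. Features of removed (bad) channels are mean-imputed
#' across epochs.
#'
#' @param recordings List of `eeg_recording` objects (e.g. from
#'   [generate_cohort()]).
#' @param settings An [extraction_settings()].
#' @param progress Print one line per subject.
#' @return Data frame: key columns `subject`, `group`, `condition`, `mover`,
#'   `epoch`, then 380 feature columns in canonical order.
#' @export
extract_features <- function(recordings, settings = extraction_settings(),
                             progress = FALSE) {
  stopifnot(length(recordings) > 0)
  set.seed(settings$seed)
  montage <- recordings[[1]]$montage
  bands <- settings$bands
  subjects <- split(recordings,
                    vapply(recordings, function(r) r$subject_id, ""))
  rows <- list()
  for (sid in names(subjects)) {
    if (progress) message("extracting subject ", sid)
    recs <- subjects[[sid]]
    base <- list()  # per-epoch: key + families + wpli matrices
    for (rec in recs) {
      bb <- settings$broadband
      rec_f <- bandpass(rec, bb[1], bb[2])
      rec_f <- rereference(rec_f, settings$reference)
      bad <- detect_bad_channels(rec_f, settings$bad_channel_z)
      bad_idx <- match(bad, montage$channel_labels)
      fs <- montage$sampling_rate
      rec_bands <- band_filtered(rec_f$data, fs, bands)
      len <- as.integer(10 * fs)
      for (ep in segment_epochs(rec_f, bad_channels = bad)) {
        span <- ((ep$epoch_index - 1L) * len + 1L):(ep$epoch_index * len)
        bf <- lapply(rec_bands, function(bm) bm[, span, drop = FALSE])
        fam <- epoch_base_features(ep, bf, settings, bad_idx)
        base[[length(base) + 1L]] <- list(
          key = data.frame(subject = ep$subject_id, group = ep$group,
                           condition = ep$condition, mover = ep$mover,
                           epoch = ep$epoch_index, stringsAsFactors = FALSE),
          fam = fam)
      }
    }
    # participant/band densities from the mean baseline wPLI matrix
    densities <- NULL
    if ("bgraph" %in% settings$classes) {
      is_base <- vapply(base, function(e) e$key$condition == "baseline",
                        TRUE)
      densities <- lapply(bands$name, function(bn) {
        mats <- lapply(base[is_base], function(e) e$fam$wpli_mats[[bn]])
        spanning_threshold(Reduce(`+`, mats) / length(mats))
      })
      names(densities) <- bands$name
    }
    for (e in base) {
      g <- if (any(c("bgraph", "wgraph") %in% settings$classes)) {
        epoch_graph_features(e$fam$wpli_mats, densities, settings)
      } else list(bgraph = numeric(0), wgraph = numeric(0))
      v <- c(e$fam$power, e$fam$peakfreq, e$fam$pe, e$fam$wpli,
             e$fam$dpli, g$bgraph, g$wgraph)
      expected <- feature_names(montage, bands)
      expected <- expected[feature_info(expected)$class %in%
                             settings$classes]
      if (!identical(names(v), expected)) {
        stop("extracted feature names do not match the canonical order")
      }
      rows[[length(rows) + 1L]] <- cbind(e$key, as.data.frame(t(v)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  feat_cols <- setdiff(names(out), c("subject", "group", "condition",
                                     "mover", "epoch"))
  if (anyNA(out[feat_cols])) {
    out[feat_cols] <- impute_missing_features(out[feat_cols])
  }
  out
}

#' Split a feature table into key columns and a numeric feature matrix
#'
#' @param table Feature table from [extract_features()].
#' @return List with `key` (subject/group/condition/mover/epoch data frame)
#'   and `x` (numeric matrix of feature columns).
#' @export
feature_matrix <- function(table) {
  key_cols <- c("subject", "group", "condition", "mover", "epoch")
  feats <- as.matrix(table[setdiff(names(table), key_cols)])
  list(key = table[intersect(key_cols, names(table))], x = feats)
}
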