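#' Cohen's d standardized mean difference
#'
#' `(mean_a - mean_b) / s_pooled`, with the pooled standard deviation using
#' `n - 1` weights. Magnitude conventions: negligible < 0.2, small < 0.5,
#' medium < 0.8, large >= 0.8.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return Signed effect size.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Label an effect-size magnitude
#' @param d Cohen's d value.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_size_label <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "negligible" else if (ad < 0.5) "small"
  else if (ad < 0.8) "medium" else "large"
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal")
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  if (any(ht$expected <= 0)) stop("non-positive expected count")
  list(statistic = unname(ht$statistic), df = 1L, p = ht$p.value)
}

#' Welch two-sample t test
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return List with `statistic`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("degenerate: both samples have zero variance")
  }
  ht <- stats::t.test(a, b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Movement-artifact feature screen
#'
#' Compares baseline (no-pain) epochs of subjects who made voluntary
#' movements against those who did not, separately for each of the 7 feature
#' classes. Within a class, all channels and frequency bands are pooled:
#' each epoch-feature cell is one observation. The two graph-theory classes
#' mix metrics of incompatible scale and sign (an artifact that lowers
#' connectivity raises path length while lowering strength, cancelling in a
#' single pooled stream), so they are tested per metric (bands pooled) and a
#' class is dropped when any of its metrics reaches the threshold; the
#' reported class statistic is the strongest metric's. Classes whose test
#' reaches the Bonferroni-corrected level `alpha / 7` are dropped from
#' downstream classification.
#'
#' @param features Feature table (as from [extract_features()]) restricted
#'   internally to `condition == "baseline"` rows.
#' @param alpha Family-wise error level before correction (default 0.05; the
#'   per-class threshold is `alpha/7 ~= 0.007`).
#' @param var_equal Use the pooled-variance Student t test (default `TRUE`,
#'   matching the classical independent-sample t test); `FALSE` for Welch.
#' @return Object of class `screening_result`: data frame with one row per
#'   class (`class`, `t`, `p`, `cohens_d`, `magnitude`, `decision`) plus
#'   attributes `retained` (kept feature names) and `threshold`.
#' @export
movement_screen <- function(features, alpha = 0.05, var_equal = TRUE) {
  base <- features[features$condition == "baseline", , drop = FALSE]
  if (!any(base$mover) || !any(!base$mover)) {
    stop("need both mover and non-mover baseline epochs")
  }
  fm <- feature_matrix(base)
  info <- feature_info(colnames(fm$x))
  classes <- intersect(feature_classes(), unique(info$class))
  # the Bonferroni family is the full 7-class feature battery
  threshold <- alpha / length(feature_classes())
  test_stream <- function(cols) {
    a <- as.vector(fm$x[fm$key$mover, cols])        # movers
    b <- as.vector(fm$x[!fm$key$mover, cols])       # non-movers
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NULL)
    # t.test itself rejects near-constant streams (e.g. ratio features
    # pinned at 1 up to rounding); treat them as untestable
    ht <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(ht)) return(NULL)
    list(t = unname(ht$statistic), p = ht$p.value, d = cohens_d(a, b))
  }
  res <- lapply(classes, function(cl) {
    cols <- info$name[info$class == cl]
    if (cl %in% c("bgraph", "wgraph")) {
      metrics <- unique(vapply(strsplit(cols, "_"), function(p)
        paste(p[-c(1, length(p))], collapse = "_"), ""))
      tests <- Filter(Negate(is.null), lapply(metrics, function(m) {
        test_stream(cols[grepl(paste0("^", cl, "_", m, "_"), cols)])
      }))
      if (length(tests) == 0) {
        stop("class ", cl, " has zero variance in both groups")
      }
      best <- tests[[which.min(vapply(tests, `[[`, 0, "p"))]]
    } else {
      best <- test_stream(cols)
      if (is.null(best)) {
        stop("class ", cl, " has zero variance in both groups")
      }
    }
    data.frame(class = cl, t = best$t, p = best$p,
               cohens_d = best$d, magnitude = effect_size_label(best$d),
               decision = if (best$p <= threshold) "drop" else "keep",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  kept_classes <- out$class[out$decision == "keep"]
  attr(out, "retained") <- info$name[info$class %in% kept_classes]
  attr(out, "threshold") <- threshold
  class(out) <- c("screening_result", "data.frame")
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Movement-artifact screen (threshold p <=",
      signif(attr(x, "threshold"), 3), "per class)\n")
  print.data.frame(x, digits = 3)
  cat(length(attr(x, "retained")), "features retained\n")
  invisible(x)
}
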