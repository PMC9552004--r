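#' Permutation test of classifier accuracy
#'
#' Builds a null distribution of accuracy by permuting condition labels and
#' re-running the full evaluation procedure (scaling, fitting, scoring) on
#' each permuted dataset. By default labels are permuted within each subject,
#' preserving per-subject epoch counts and between-subject structure; a
#' global epoch-level shuffle is available. The p value uses the add-one
#' estimator `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never
#' exactly zero.
#'
#' @param pipeline Function `(x, y, subjects) -> accuracy` implementing the
#'   full evaluation (e.g. a wrapper around [evaluate_on_validation()] or
#'   [loso_cv()]).
#' @param x Feature matrix.
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @param n_perm Number of permutations (default 10000; reduce for
#'   desk-scale runs).
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @param unit `"within_subject"` (default) or `"global"` label shuffling.
#' @return Object of class `permutation_result`: `observed`, `null`
#'   (numeric vector), `p`, `n_perm`, `alpha`, `significant`, `seed`.
#' @export
permutation_test <- function(pipeline, x, y, subjects, n_perm = 10000,
                             alpha = 0.01, seed,
                             unit = c("within_subject", "global")) {
  unit <- match.arg(unit)
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  y <- as.character(y)
  subjects <- as.character(subjects)
  observed <- pipeline(x, y, subjects)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- if (unit == "global") {
      sample(y)
    } else {
      out <- y
      for (sid in unique(subjects)) {
        idx <- which(subjects == sid)
        out[idx] <- y[idx][sample.int(length(idx))]
      }
      out
    }
    pipeline(x, yp, subjects)
  }, 0)
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p = p, n_perm = n_perm,
                 alpha = alpha, significant = p <= alpha, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed accuracy ", round(x$observed, 3),
      ", p = ", signif(x$p, 3), " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Bootstrap percentile confidence interval for classifier accuracy
#'
#' Resamples per-epoch prediction records with replacement and takes the
#' 2.5 and 97.5 percentiles of the resampled accuracies. A subject-level
#' bootstrap (resampling whole subjects) is available.
#'
#' @param correct Logical (or 0/1) vector: was each epoch classified
#'   correctly.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param subjects Subject ids, required for `unit = "subject"`.
#' @param unit `"epoch"` (default) or `"subject"` resampling.
#' @param level Confidence level (default 0.95).
#' @return Object of class `bootstrap_ci`: `estimate`, `lower`, `upper`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(correct, n_boot = 10000, seed, subjects = NULL,
                         unit = c("epoch", "subject"), level = 0.95) {
  unit <- match.arg(unit)
  if (missing(seed)) stop("a seed is required")
  correct <- as.logical(correct)
  n <- length(correct)
  if (n < 2) stop("need at least 2 prediction records")
  set.seed(seed)
  if (unit == "epoch") {
    accs <- vapply(seq_len(n_boot), function(i) {
      mean(correct[sample.int(n, n, replace = TRUE)])
    }, 0)
  } else {
    if (is.null(subjects)) stop("subject-level bootstrap needs subject ids")
    by_sub <- split(correct, as.character(subjects))
    accs <- vapply(seq_len(n_boot), function(i) {
      mean(unlist(by_sub[sample.int(length(by_sub), length(by_sub),
                                    replace = TRUE)]))
    }, 0)
  }
  qs <- stats::quantile(accs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(estimate = mean(correct), lower = qs[1], upper = qs[2],
                 n_boot = n_boot, seed = seed, level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("<bootstrap_ci> ", round(x$estimate, 3), " [",
      round(x$lower, 3), ", ", round(x$upper, 3), "] (",
      x$n_boot, " resamples)\n", sep = "")
  invisible(x)
}

#' Compare two bootstrap CIs by overlap
#'
#' Two models (or groups) are deemed different only when their confidence
#' intervals do not overlap.
#'
#' @param a,b `bootstrap_ci` objects (or lists with `lower`/`upper`).
#' @return `"different"` or `"not_different"`.
#' @export
ci_overlap_compare <- function(a, b) {
  if (a$upper < b$lower || b$upper < a$lower) "different" else "not_different"
}
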