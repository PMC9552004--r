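#' Classifier specification
#'
#' @param family `"lda"`, `"svm"`, `"tree"`, or `"logistic"` (L1-penalized).
#' @param kernel SVM kernel, `"linear"` or `"rbf"`.
#' @param C Regularization parameter (SVM cost / inverse logistic penalty).
#' @param criterion Decision-tree split criterion, `"gini"` or `"entropy"`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("lda", "svm", "tree", "logistic"),
                       kernel = c("linear", "rbf"), C = 1,
                       criterion = c("gini", "entropy")) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  criterion <- match.arg(criterion)
  if (C <= 0) stop("C must be positive")
  structure(list(family = family, kernel = kernel, C = C,
                 criterion = criterion),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- switch(x$family,
                  svm = paste0(" (", x$kernel, ", C=", x$C, ")"),
                  logistic = paste0(" (L1, C=", x$C, ")"),
                  tree = paste0(" (", x$criterion, ")"),
                  "")
  cat("<model_spec> ", x$family, extra, "\n", sep = "")
  invisible(x)
}

#' The hyperparameter sweep grid for C
#' @return Numeric vector `{0.1, ..., 1.0, 2, 5, 10}`.
#' @export
c_grid <- function() c(seq(0.1, 1, by = 0.1), 2, 5, 10)

#' Standard-scaler fit on training rows
#'
#' Per-feature centering and scaling to unit training standard deviation.
#' Zero-variance features are centered but left unscaled (all zeros) and
#' flagged with a warning.
#'
#' @param train Training feature matrix.
#' @param warn Warn on constant columns (default TRUE).
#' @return Object of class `feature_scaler` with `center`, `scale`,
#'   `constant` (logical per feature).
#' @export
fit_scaler <- function(train, warn = TRUE) {
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  constant <- !is.finite(scale) | scale == 0
  if (any(constant) && warn) {
    warning(sum(constant), " constant feature(s) passed through centered only")
  }
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "feature_scaler")
}

#' Apply a fitted scaler
#' @param scaler A `feature_scaler`.
#' @param x Feature matrix with the same columns as the training matrix.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, x) {
  if (!identical(names(scaler$center), colnames(x))) {
    stop("feature-name mismatch between scaler and data")
  }
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Standard scaling fit on training rows, applied to both partitions
#'
#' @param train Training feature matrix (scaler is fit here only).
#' @param apply_to Optional second matrix scaled with the training
#'   parameters.
#' @return List with `train`, `apply_to` (NULL if absent), and `scaler`.
#' @export
standard_scale <- function(train, apply_to = NULL) {
  sc <- fit_scaler(train)
  list(train = apply_scaler(sc, train),
       apply_to = if (!is.null(apply_to)) apply_scaler(sc, apply_to),
       scaler = sc)
}

condition_levels <- function() c("baseline", "cpt")

# L1 logistic for a single feature (glmnet requires >= 2 columns):
# minimize mean log-loss + lambda * |beta| via BFGS on a smoothed |.|
l1_logistic_1d <- function(x, y01, lambda) {
  obj <- function(par) {
    eta <- par[1] + par[2] * x
    mean(log1p(exp(-(2 * y01 - 1) * eta))) + lambda * sqrt(par[2]^2 + 1e-12)
  }
  fit <- stats::optim(c(0, 0), obj, method = "BFGS")
  fit$par
}

#' Fit a classifier
#'
#' Dispatches to `MASS::lda`, `e1071::svm`, `rpart::rpart`, or L1-penalized
#' logistic regression (`glmnet`; the penalty `lambda = 1/(C*n)` matches the
#' usual inverse-regularization meaning of C). Inputs are assumed already
#' standard-scaled.
#'
#' @param spec A [model_spec()].
#' @param x Feature matrix (rows = epochs).
#' @param y Condition labels (`"baseline"`/`"cpt"`).
#' @return Object of class `fitted_model`.
#' @export
fit_model <- function(spec, x, y) {
  y <- factor(y, levels = condition_levels())
  if (length(unique(y)) < 2) stop("training data lacks a class")
  fit <- switch(
    spec$family,
    lda = MASS::lda(x, grouping = y),
    svm = e1071::svm(x, y,
                     kernel = if (spec$kernel == "rbf") "radial" else "linear",
                     cost = spec$C, scale = FALSE),
    tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = if (spec$criterion == "gini")
                     "gini" else "information"),
                   control = rpart::rpart.control(xval = 0))
    },
    logistic = {
      n <- nrow(x)
      lambda <- 1 / (spec$C * n)
      if (ncol(x) == 1) {
        l1_logistic_1d(x[, 1], as.integer(y) - 1L, lambda)
      } else {
        withCallingHandlers(
          glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         lambda = sort(lambda * c(100, 10, 1),
                                       decreasing = TRUE),
                         standardize = FALSE, maxit = 5e5),
          # tiny LOSO folds are routine here; glmnet's small-class notice
          # would otherwise flood every sweep
          warning = function(w) {
            if (grepl("dangerous ground", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
      }
    })
  structure(list(spec = spec, fit = fit, features = colnames(x),
                 n_train = nrow(x)),
            class = "fitted_model")
}

#' Predict condition labels
#' @param model A `fitted_model`.
#' @param x Feature matrix with the training columns.
#' @return Character vector of `"baseline"`/`"cpt"`.
#' @export
predict_model <- function(model, x) {
  if (!identical(model$features, colnames(x))) {
    stop("feature-name mismatch between model and data")
  }
  spec <- model$spec
  out <- switch(
    spec$family,
    lda = as.character(stats::predict(model$fit, x)$class),
    svm = as.character(stats::predict(model$fit, x)),
    tree = {
      df <- as.data.frame(x, check.names = FALSE)
      as.character(stats::predict(model$fit, df, type = "class"))
    },
    logistic = {
      if (ncol(x) == 1) {
        eta <- model$fit[1] + model$fit[2] * x[, 1]
        ifelse(eta > 0, "cpt", "baseline")
      } else {
        lambda <- 1 / (spec$C * model$n_train)
        as.character(stats::predict(model$fit, x, type = "class",
                                    s = lambda))
      }
    })
  out
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's epochs are held out, the scaler and
#' model are fit on the remaining subjects, and the fold accuracy is the
#' proportion of the held-out subject's epochs classified correctly. The
#' reported accuracy is the unweighted mean over subjects. Training and test
#' subject sets are asserted disjoint in every fold.
#'
#' @param spec A [model_spec()].
#' @param x Feature matrix.
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @return Object of class `eval_result`: list with `fold_accuracy` (named
#'   per subject), `accuracy` (mean), `spec`, `predictions` (per-epoch data
#'   frame).
#' @export
loso_cv <- function(spec, x, y, subjects) {
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  if (length(ids) < 2) stop("LOSO needs at least 2 subjects")
  y <- as.character(y)
  fold_acc <- numeric(length(ids))
  names(fold_acc) <- ids
  preds <- list()
  for (sid in ids) {
    test <- subjects == sid
    stopifnot(!any(subjects[!test] == sid))  # leakage guard
    if (length(unique(y[!test])) < 2) {
      stop("training partition of fold ", sid, " lacks a class")
    }
    sc <- fit_scaler(x[!test, , drop = FALSE], warn = FALSE)
    fit <- fit_model(spec, apply_scaler(sc, x[!test, , drop = FALSE]),
                     y[!test])
    p <- predict_model(fit, apply_scaler(sc, x[test, , drop = FALSE]))
    fold_acc[sid] <- mean(p == y[test])
    preds[[sid]] <- data.frame(subject = sid, truth = y[test], pred = p,
                               correct = p == y[test],
                               stringsAsFactors = FALSE)
  }
  structure(list(fold_accuracy = fold_acc, accuracy = mean(fold_acc),
                 spec = spec, predictions = do.call(rbind, preds)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", x$spec$family, ": mean LOSO accuracy ",
      round(x$accuracy, 3), " over ", length(x$fold_accuracy), " folds\n",
      sep = "")
  invisible(x)
}

sweep_specs <- function(families = c("lda", "svm", "tree", "logistic")) {
  specs <- list()
  if ("lda" %in% families) specs <- c(specs, list(model_spec("lda")))
  if ("svm" %in% families) {
    for (kernel in c("linear", "rbf")) {
      for (C in c_grid()) {
        specs <- c(specs, list(model_spec("svm", kernel = kernel, C = C)))
      }
    }
  }
  if ("tree" %in% families) {
    for (crit in c("gini", "entropy")) {
      specs <- c(specs, list(model_spec("tree", criterion = crit)))
    }
  }
  if ("logistic" %in% families) {
    for (C in c_grid()) {
      specs <- c(specs, list(model_spec("logistic", C = C)))
    }
  }
  specs
}

#' Hyperparameter and model-family sweep under LOSO
#'
#' Evaluates LDA (defaults), SVM (linear and RBF kernels over the C grid),
#' decision trees (gini/entropy) and L1 logistic regression (C grid) by
#' LOSO mean accuracy. Ties are broken toward smaller C, then linear before
#' RBF, then family order as listed, so the result is deterministic.
#'
#' @param x Feature matrix.
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @param families Model families to include.
#' @return List with `table` (ranked data frame of all evaluations),
#'   `best` (best `model_spec` overall), `best_per_family` (named list).
#' @export
model_sweep <- function(x, y, subjects,
                        families = c("lda", "svm", "tree", "logistic")) {
  specs <- sweep_specs(families)
  if (length(specs) == 0) stop("empty sweep grid")
  rows <- lapply(specs, function(sp) {
    acc <- loso_cv(sp, x, y, subjects)$accuracy
    data.frame(family = sp$family,
               kernel = if (sp$family == "svm") sp$kernel else NA,
               C = if (sp$family %in% c("svm", "logistic")) sp$C else NA,
               criterion = if (sp$family == "tree") sp$criterion else NA,
               accuracy = acc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fam_rank <- match(tab$family, c("lda", "svm", "tree", "logistic"))
  kern_rank <- ifelse(is.na(tab$kernel), 0, match(tab$kernel,
                                                  c("linear", "rbf")))
  ord <- order(-tab$accuracy, ifelse(is.na(tab$C), 0, tab$C), kern_rank,
               fam_rank)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  pick <- function(row) {
    model_spec(row$family,
               kernel = if (!is.na(row$kernel)) row$kernel else "linear",
               C = if (!is.na(row$C)) row$C else 1,
               criterion = if (!is.na(row$criterion)) row$criterion
               else "gini")
  }
  best_per_family <- lapply(split(tab, tab$family), function(t) pick(t[1, ]))
  list(table = tab, best = pick(tab[1, ]),
       best_per_family = best_per_family[unique(tab$family)])
}

#' Split a dataset into train/test and validation partitions
#'
#' Default subject-level split: all epochs of a subject fall on one side,
#' preventing within-subject leakage between partitions. An epoch-level
#' split is available behind `level = "epoch"`.
#'
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @param fraction Training fraction (default 0.8).
#' @param level `"subject"` (default) or `"epoch"`.
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `validation`.
#' @export
split_train_validation <- function(y, subjects, fraction = 0.8,
                                   level = c("subject", "epoch"), seed) {
  level <- match.arg(level)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- length(y)
  if (level == "subject") {
    ids <- unique(as.character(subjects))
    n_train <- floor(fraction * length(ids))
    if (n_train < 1 || n_train >= length(ids)) {
      stop("fraction leaves an empty partition")
    }
    train_ids <- sample(ids, n_train)
    train <- which(subjects %in% train_ids)
    validation <- which(!subjects %in% train_ids)
  } else {
    n_train <- floor(fraction * n)
    train <- sort(sample(seq_len(n), n_train))
    validation <- setdiff(seq_len(n), train)
  }
  for (part in list(train, validation)) {
    if (length(unique(y[part])) < 2) {
      stop("a partition contains a single class; use a different seed or size")
    }
  }
  list(train = train, validation = validation)
}

#' Final evaluation on the held-out validation partition
#'
#' Fits the scaler and model on the training partition and scores the
#' validation epochs once.
#'
#' @param spec A [model_spec()].
#' @param x Feature matrix.
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @param split A list with `train` and `validation` indices
#'   (from [split_train_validation()]).
#' @return List with `accuracy`, `predictions` (per-epoch data frame with
#'   `subject`, `truth`, `pred`, `correct`), `model` (the `fitted_model`),
#'   and `scaler`.
#' @export
evaluate_on_validation <- function(spec, x, y, subjects, split) {
  tr <- split$train
  va <- split$validation
  y <- as.character(y)
  sc <- fit_scaler(x[tr, , drop = FALSE], warn = FALSE)
  fit <- fit_model(spec, apply_scaler(sc, x[tr, , drop = FALSE]), y[tr])
  p <- predict_model(fit, apply_scaler(sc, x[va, , drop = FALSE]))
  list(accuracy = mean(p == y[va]),
       predictions = data.frame(subject = as.character(subjects[va]),
                                truth = y[va], pred = p,
                                correct = p == y[va],
                                stringsAsFactors = FALSE),
       model = fit, scaler = sc)
}

#' Build the standard feature subsets for final-model runs
#'
#' `all` retained features; each retained feature class alone; theta-band
#' permutation entropy at each single electrode.
#'
#' @param retained Character vector of retained feature names.
#' @return Named list of feature-name vectors.
#' @export
classification_subsets <- function(retained) {
  info <- feature_info(retained)
  subsets <- list(all = retained)
  for (cl in intersect(feature_classes(), unique(info$class))) {
    subsets[[paste0("class_", cl)]] <- info$name[info$class == cl]
  }
  theta_pe <- info[info$class == "pe" & info$band == "theta", ]
  for (k in seq_len(nrow(theta_pe))) {
    subsets[[paste0("electrode_", theta_pe$channel[k])]] <- theta_pe$name[k]
  }
  subsets
}

#' Run final models on feature subsets
#'
#' For each subset and model, reports the LOSO accuracy on the training
#' partition and the single validation accuracy.
#'
#' @param specs Named list of `model_spec`s (e.g. best SVM and best
#'   logistic).
#' @param x Feature matrix.
#' @param y Condition labels.
#' @param subjects Subject id per row.
#' @param split Partition from [split_train_validation()].
#' @param subsets Named list of feature-name vectors
#'   (default: [classification_subsets()] on all columns).
#' @return Data frame with one row per model x subset:
#'   `model`, `subset`, `n_features`, `loso_accuracy`, `validation_accuracy`.
#' @export
feature_subset_runs <- function(specs, x, y, subjects, split,
                                subsets = classification_subsets(colnames(x))) {
  if (any(vapply(subsets, length, 1L) == 0)) stop("empty feature subset")
  missing_feats <- setdiff(unlist(subsets), colnames(x))
  if (length(missing_feats)) {
    stop("subset references unavailable features: ",
         paste(utils::head(missing_feats, 3), collapse = ", "))
  }
  if (is.null(names(specs))) names(specs) <- vapply(specs, function(s)
    s$family, "")
  rows <- list()
  for (mname in names(specs)) {
    for (sname in names(subsets)) {
      cols <- subsets[[sname]]
      xs <- x[, cols, drop = FALSE]
      tr <- split$train
      lo <- loso_cv(specs[[mname]], xs[tr, , drop = FALSE], y[tr],
                    subjects[tr])
      ev <- evaluate_on_validation(specs[[mname]], xs, y, subjects, split)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mname, subset = sname, n_features = length(cols),
        loso_accuracy = lo$accuracy, validation_accuracy = ev$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature importance from L1 logistic-regression weights
#'
#' Ranks features by absolute model weight (inputs were standard-scaled, so
#' weights are comparable) and returns the top fraction with sign and
#' feature metadata. Positive weights predict the pain (CPT) condition.
#'
#' @param model A `fitted_model` with `family == "logistic"`.
#' @param top_fraction Fraction of features to return (default 0.10; the
#'   count is `floor(top_fraction * n_features)`, at least 1 — 19 entries
#'   for a 192-feature retained set).
#' @return Data frame `name`, `weight`, `rank`, `class`, `band`, `channel`.
#' @export
logistic_importance <- function(model, top_fraction = 0.10) {
  stopifnot(inherits(model, "fitted_model"),
            model$spec$family == "logistic")
  if (length(model$features) == 1) {
    w <- model$fit[2]
    names(w) <- model$features
  } else {
    lambda <- 1 / (model$spec$C * model$n_train)
    cf <- as.matrix(stats::coef(model$fit, s = lambda))
    w <- cf[-1, 1]
    names(w) <- model$features
  }
  if (all(w == 0)) stop("all weights are zero (model fully sparsified)")
  n_top <- max(1, floor(top_fraction * length(w)))
  ord <- order(-abs(w), names(w))
  top <- w[ord][seq_len(n_top)]
  info <- feature_info(names(top))
  data.frame(name = names(top), weight = unname(top),
             rank = seq_len(n_top), class = info$class, band = info$band,
             channel = info$channel, stringsAsFactors = FALSE)
}
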