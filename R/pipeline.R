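#' Full-run configuration
#'
#' Bundles every stage's parameters and seeds; a run is reproducible from
#' its config alone.
#'
#' @param cohort A [cohort_config()].
#' @param extraction An [extraction_settings()].
#' @param families Model families for the sweep.
#' @param split_fraction Training fraction of the 80:20 split.
#' @param split_level `"subject"` or `"epoch"`.
#' @param n_perm Permutations for significance testing.
#' @param n_boot Bootstrap resamples for CIs.
#' @param seeds Named integer seeds for `split`, `permutation`, `bootstrap`.
#' @param out_dir Optional output directory; when set, the feature CSV,
#'   screening JSON, results JSON and a text summary are written there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(seed = 1),
                       extraction = extraction_settings(),
                       families = c("lda", "svm", "tree", "logistic"),
                       split_fraction = 0.8,
                       split_level = "subject",
                       n_perm = 10000, n_boot = 10000,
                       seeds = c(split = 11, permutation = 12,
                                 bootstrap = 13),
                       out_dir = NULL) {
  structure(list(cohort = cohort, extraction = extraction,
                 families = families, split_fraction = split_fraction,
                 split_level = split_level, n_perm = n_perm,
                 n_boot = n_boot, seeds = seeds, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; `cohort`
#' and `extraction` are nested maps passed to their constructors ( `effect`
#' inside `cohort` builds an [effect_spec()]).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$effect)) {
    cohort_args$effect <- do.call(effect_spec, cohort_args$effect)
  }
  if (!is.null(cohort_args$epochs_per_condition)) {
    cohort_args$epochs_per_condition <-
      unlist(cohort_args$epochs_per_condition)
  }
  args <- list(cohort = do.call(cohort_config, cohort_args),
               extraction = do.call(extraction_settings,
                                    y$extraction %||% list()))
  for (k in c("families", "split_fraction", "split_level", "n_perm",
              "n_boot", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$seeds)) args$seeds <- unlist(y$seeds)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_group <- function(features, config, group_name) {
  grp <- features[features$group == group_name, , drop = FALSE]
  fm <- feature_matrix(grp)
  y <- fm$key$condition
  subjects <- fm$key$subject

  # movement screen (needs both mover and non-mover baseline epochs)
  base <- grp[grp$condition == "baseline", ]
  screening <- NULL
  retained <- colnames(fm$x)
  if (any(base$mover) && any(!base$mover)) {
    screening <- movement_screen(grp)
    retained <- attr(screening, "retained")
  }
  x <- fm$x[, retained, drop = FALSE]

  split <- split_train_validation(y, subjects,
                                  fraction = config$split_fraction,
                                  level = config$split_level,
                                  seed = config$seeds[["split"]])
  tr <- split$train
  sweep <- model_sweep(x[tr, , drop = FALSE], y[tr], subjects[tr],
                       families = config$families)
  final_specs <- sweep$best_per_family[
    intersect(c("svm", "logistic"), names(sweep$best_per_family))]
  if (length(final_specs) == 0) final_specs <- list(best = sweep$best)

  evals <- lapply(final_specs, function(sp) {
    ev <- evaluate_on_validation(sp, x, y, subjects, split)
    perm <- permutation_test(
      function(xx, yy, ss) {
        evaluate_on_validation(sp, xx, yy, ss, split)$accuracy
      },
      x, y, subjects, n_perm = config$n_perm,
      seed = config$seeds[["permutation"]])
    boot <- bootstrap_ci(ev$predictions$correct, n_boot = config$n_boot,
                         seed = config$seeds[["bootstrap"]],
                         subjects = ev$predictions$subject)
    list(accuracy = ev$accuracy, permutation = perm, bootstrap = boot,
         model = ev$model)
  })

  subsets <- classification_subsets(retained)
  subset_table <- feature_subset_runs(final_specs, x, y, subjects, split,
                                      subsets)

  importance <- NULL
  if ("logistic" %in% names(final_specs)) {
    importance <- logistic_importance(evals$logistic$model)
  }

  list(group = group_name, screening = screening, retained = retained,
       sweep_table = sweep$table, final_specs = final_specs,
       evaluations = evals, subset_table = subset_table,
       importance = importance, split = split)
}

#' Run the complete analysis pipeline
#'
#' Simulate (or ingest) a cohort, extract the 380-feature table, screen for
#' movement-affected feature classes, and — separately per group (pain,
#' healthy), as the groups have distinct resting EEG — sweep classifiers
#' under LOSO on the training partition, evaluate the best SVM and logistic
#' model on the held-out validation partition, attach permutation-test p
#' values and bootstrap CIs, run the feature-subset and per-electrode
#' analyses, and rank logistic feature importance.
#'
#' @param config A [run_config()].
#' @param recordings Optional pre-generated recordings (default: simulate
#'   from `config$cohort`).
#' @param progress Print stage progress.
#' @return Object of class `run_report`: list with `features`, and per-group
#'   results under `groups`.
#' @export
run_full_analysis <- function(config = run_config(), recordings = NULL,
                              progress = FALSE) {
  say <- function(...) if (progress) message(...)
  say("simulating cohort")
  if (is.null(recordings)) recordings <- generate_cohort(config$cohort)
  say("extracting features")
  features <- extract_features(recordings, config$extraction,
                               progress = progress)
  groups <- list()
  for (g in unique(features$group)) {
    say("analyzing group ", g)
    groups[[g]] <- analyze_group(features, config, g)
  }
  report <- structure(list(features = features, groups = groups,
                           config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(report$features, file.path(dir, "features.csv"))
  for (g in names(report$groups)) {
    res <- report$groups[[g]]
    write_screening_json(res$screening,
                         file.path(dir, paste0("screening_", g, ".json")))
    utils::write.csv(res$subset_table,
                     file.path(dir, paste0("accuracy_", g, ".csv")),
                     row.names = FALSE)
    payload <- list(
      group = g,
      retained_features = length(res$retained),
      models = lapply(res$evaluations, function(e) {
        list(accuracy = e$accuracy,
             p = e$permutation$p,
             ci = c(e$bootstrap$lower, e$bootstrap$upper))
      }),
      importance = res$importance)
    jsonlite::write_json(payload,
                         file.path(dir, paste0("results_", g, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(format(report), con)
  invisible(dir)
}

#' @export
format.run_report <- function(x, ...) {
  lines <- c(sprintf("Epochs: %d (%d features)", nrow(x$features),
                     sum(!names(x$features) %in%
                           c("subject", "group", "condition", "mover",
                             "epoch"))))
  for (g in names(x$groups)) {
    res <- x$groups[[g]]
    lines <- c(lines, sprintf("Group %s: %d features retained after screen",
                              g, length(res$retained)))
    for (m in names(res$evaluations)) {
      e <- res$evaluations[[m]]
      lines <- c(lines, sprintf(
        "  %s: validation accuracy %.1f%% (95%% CI %.1f-%.1f%%), p = %.4g",
        m, 100 * e$accuracy, 100 * e$bootstrap$lower,
        100 * e$bootstrap$upper, e$permutation$p))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.run_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
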