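# linearly separable multi-subject feature set
separable_data <- function(n_sub = 8, epochs = 6, p = 5, gap = 10,
                           seed = 61) {
  set.seed(seed)
  n <- n_sub * epochs
  subjects <- rep(sprintf("s%02d", seq_len(n_sub)), each = epochs)
  y <- rep(rep(c("baseline", "cpt"), length.out = epochs), n_sub)
  x <- matrix(rnorm(n * p), n)
  x[y == "cpt", 1] <- x[y == "cpt", 1] + gap
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y, subjects = subjects)
}

test_that("standard scaling normalizes training columns and transfers affinely", {
  set.seed(62)
  tr <- matrix(rnorm(60, mean = 5, sd = 3), 20)
  colnames(tr) <- c("a", "b", "c")
  te <- tr + 2
  out <- standard_scale(tr, te)
  expect_equal(unname(colMeans(out$train)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out$train, 2, sd)), rep(1, 3))
  # a constant shift in raw units stays a constant shift in SD units
  expect_equal(out$apply_to - out$train,
               matrix(rep(2 / out$scaler$scale, each = 20), 20),
               ignore_attr = TRUE)

  const <- cbind(tr, d = 7)
  expect_warning(sc <- fit_scaler(const), "constant")
  expect_equal(unname(apply_scaler(sc, const)[, "d"]), rep(0, 20))

  expect_error(apply_scaler(fit_scaler(tr), te[, c(2, 1, 3)]), "mismatch")
})

test_that("LOSO folds partition epochs by subject and score separable data perfectly", {
  d <- separable_data()
  for (family in c("lda", "svm", "logistic", "tree")) {
    ev <- loso_cv(model_spec(family, C = 1), d$x, d$y, d$subjects)
    expect_length(ev$fold_accuracy, 8)
    expect_equal(ev$accuracy, 1, tolerance = 1e-12,
                 info = family)
  }
  ev <- loso_cv(model_spec("lda"), d$x, d$y, d$subjects)
  expect_equal(sort(unique(ev$predictions$subject)), unique(d$subjects))
  expect_equal(nrow(ev$predictions), length(d$y))

  # a fold whose training partition lacks a class errors
  d2 <- separable_data(n_sub = 2)
  y_bad <- ifelse(d2$subjects == "s01", "baseline", "cpt")
  expect_error(loso_cv(model_spec("lda"), d2$x, y_bad, d2$subjects),
               "lacks a class")
})

test_that("label-independent features score near prevalence under LOSO", {
  set.seed(63)
  d <- separable_data(gap = 0, n_sub = 10, epochs = 8)
  ev <- loso_cv(model_spec("lda"), d$x, d$y, d$subjects)
  expect_lt(abs(ev$accuracy - 0.5), 0.15)
})

test_that("the sweep grid has the printed shape and deterministic tie-breaks", {
  specs <- eegpain:::sweep_specs()
  fam <- vapply(specs, function(s) s$family, "")
  expect_equal(sum(fam == "svm"), 26)       # 13 C values x 2 kernels
  expect_equal(sum(fam == "logistic"), 13)
  expect_equal(sum(fam == "tree"), 2)
  expect_equal(sum(fam == "lda"), 1)
  expect_equal(c_grid(), c(seq(0.1, 1, 0.1), 2, 5, 10))

  # all-perfect accuracies tie; the winner is the smallest C, linear first
  d <- separable_data()
  sw <- model_sweep(d$x, d$y, d$subjects, families = c("svm", "logistic"))
  expect_equal(sw$table$accuracy[1], 1)
  expect_equal(sw$best$C, 0.1)
  top_svm <- sw$table[sw$table$family == "svm", ][1, ]
  expect_equal(top_svm$kernel, "linear")

  expect_error(model_sweep(d$x, d$y, d$subjects, families = character()),
               "empty")
})

test_that("radially separable data favors the RBF kernel", {
  set.seed(64)
  n_sub <- 10; epochs <- 10
  subjects <- rep(sprintf("s%02d", 1:n_sub), each = epochs)
  n <- n_sub * epochs
  r <- ifelse(seq_len(n) %% 2 == 0, 1, 3) + rnorm(n, sd = 0.2)
  th <- runif(n, 0, 2 * pi)
  x <- cbind(f1 = r * cos(th), f2 = r * sin(th))
  y <- ifelse(seq_len(n) %% 2 == 0, "cpt", "baseline")
  acc_rbf <- loso_cv(model_spec("svm", kernel = "rbf", C = 1), x, y,
                     subjects)$accuracy
  acc_lin <- loso_cv(model_spec("svm", kernel = "linear", C = 1), x, y,
                     subjects)$accuracy
  expect_gt(acc_rbf, acc_lin + 0.2)
})

test_that("train/validation splits respect the subject level and the seed", {
  d <- separable_data(n_sub = 10, epochs = 4)
  sp <- split_train_validation(d$y, d$subjects, seed = 65)
  expect_length(unique(d$subjects[sp$train]), 8)
  expect_length(unique(d$subjects[sp$validation]), 2)
  expect_length(intersect(d$subjects[sp$train],
                          d$subjects[sp$validation]), 0)
  sp2 <- split_train_validation(d$y, d$subjects, seed = 65)
  expect_identical(sp, sp2)

  spe <- split_train_validation(d$y, d$subjects, level = "epoch",
                                seed = 66)
  expect_length(spe$train, floor(0.8 * length(d$y)))
  expect_length(intersect(spe$train, spe$validation), 0)
})

test_that("validation evaluation is deterministic and honest about permuted labels", {
  d <- separable_data(n_sub = 10, epochs = 6)
  sp <- split_train_validation(d$y, d$subjects, seed = 67)
  spec <- model_spec("svm", kernel = "linear", C = 1)
  e1 <- evaluate_on_validation(spec, d$x, d$y, d$subjects, sp)
  e2 <- evaluate_on_validation(spec, d$x, d$y, d$subjects, sp)
  expect_identical(e1$accuracy, e2$accuracy)
  expect_equal(e1$accuracy, 1)
  expect_equal(nrow(e1$predictions), length(sp$validation))

  # permuting validation labels pushes accuracy to prevalence
  set.seed(68)
  accs <- replicate(30, {
    yy <- d$y
    yy[sp$validation] <- sample(yy[sp$validation])
    evaluate_on_validation(spec, d$x, yy, d$subjects, sp)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("subset runs cover classes and electrodes with correct counting", {
  retained <- feature_info(feature_names())
  retained <- retained$name[retained$class %in%
                              c("peakfreq", "pe", "dpli", "bgraph")]
  subsets <- classification_subsets(retained)
  # all + 4 class subsets + 19 theta-PE electrodes
  expect_length(subsets, 24)
  expect_length(subsets$all, 192)
  expect_length(subsets$electrode_Cz, 1)

  set.seed(69)
  n_sub <- 6; epochs <- 4
  subjects <- rep(sprintf("s%02d", 1:n_sub), each = epochs)
  y <- rep(c("baseline", "cpt"), length.out = n_sub * epochs)
  x <- matrix(rnorm(n_sub * epochs * length(retained)), n_sub * epochs)
  colnames(x) <- retained
  x[y == "cpt", "pe_theta_P3"] <- x[y == "cpt", "pe_theta_P3"] + 3
  sp <- split_train_validation(y, subjects, seed = 70)
  runs <- feature_subset_runs(list(svm = model_spec("svm", C = 1)), x, y,
                              subjects, sp)
  expect_equal(nrow(runs), 24)
  el <- runs[startsWith(runs$subset, "electrode_"), ]
  expect_equal(el$subset[which.max(el$loso_accuracy)], "electrode_P3")

  expect_error(feature_subset_runs(list(model_spec("lda")), x, y, subjects,
                                   sp, subsets = list(bad = "nope")),
               "unavailable")
})

test_that("logistic importance ranks a planted effect first with the documented count", {
  set.seed(71)
  p <- 192
  nm <- feature_info(feature_names())
  nm <- nm$name[nm$class %in% c("peakfreq", "pe", "dpli", "bgraph")]
  n <- 120
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- nm
  y <- rep(c("baseline", "cpt"), length.out = n)
  x[y == "cpt", "pe_theta_Cz"] <- x[y == "cpt", "pe_theta_Cz"] + 2.5
  fit <- fit_model(model_spec("logistic", C = 1), x, y)
  imp <- logistic_importance(fit)
  expect_equal(nrow(imp), 19)          # floor(0.10 * 192)
  expect_equal(imp$name[1], "pe_theta_Cz")
  expect_gt(imp$weight[1], 0)          # positive weights predict pain
  expect_equal(imp$band[1], "theta")

  # the single-feature logistic path works end to end
  x1 <- x[, "pe_theta_Cz", drop = FALSE]
  f1 <- fit_model(model_spec("logistic", C = 1), x1, y)
  acc <- mean(predict_model(f1, x1) == y)
  expect_gt(acc, 0.85)
  imp1 <- logistic_importance(f1)
  expect_equal(nrow(imp1), 1)
})
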