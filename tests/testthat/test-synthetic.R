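test_that("identical seeds give bit-identical cohorts", {
  cfg <- function() cohort_config(n_subjects_per_group = 1,
                                  epochs_per_condition = c(baseline = 1,
                                                           cpt = 1),
                                  movement_fraction = 1, seed = 101)
  r1 <- generate_cohort(cfg())
  r2 <- generate_cohort(cfg())
  expect_identical(r1, r2)
  expect_length(r1, 4)   # 2 groups x 1 subject x 2 conditions

  conds <- vapply(r1, function(r) r$condition, "")
  expect_equal(sort(unique(conds)), c("baseline", "cpt"))
  expect_true(all(vapply(r1, function(r) nrow(r$data) == 19, TRUE)))
  # epoch yield matches the configured counts
  expect_equal(ncol(r1[[1]]$data), 3000)

  expect_error(cohort_config(n_subjects_per_group = 0, seed = 1), ">= 1")
  expect_error(cohort_config(movement_fraction = 2, seed = 1), "movement")
  expect_error(cohort_config(n_subjects_per_group = 2), "seed")
})

test_that("motor-artifact injection adds energy, flags the mover, and leaves the input alone", {
  rec <- toy_recording(duration_s = 20, seed = 102)
  snapshot <- rec$data

  same <- inject_motor_artifact(rec, burst_rate = 6, amplitude = 0,
                                seed = 103)
  expect_equal(same$data, rec$data)
  expect_true(same$mover)

  loud <- inject_motor_artifact(rec, burst_rate = 20, amplitude = 200,
                                seed = 104)
  bp_in <- bandpass(rec$data, 1, 50, fs = 300)
  bp_out <- bandpass(loud$data, 1, 50, fs = 300)
  expect_gt(sum(bp_out^2), sum(bp_in^2))
  expect_identical(rec$data, snapshot)   # input unchanged
  expect_false(rec$mover)

  cpt <- rec
  cpt$condition <- "cpt"
  expect_error(inject_motor_artifact(cpt, 6, 10, seed = 1), "baseline")
  expect_error(inject_motor_artifact(rec, -1, 10, seed = 1),
               "non-negative")
})

test_that("a zero effect leaves baseline and CPT theta complexity exchangeable", {
  # two-sample t on per-epoch theta PE at Cz, repeated over fresh null
  # cohorts: p values should be roughly uniform
  ps <- replicate(30, {
    cfg <- cohort_config(n_subjects_per_group = 1,
                         epochs_per_condition = c(baseline = 3, cpt = 3),
                         seed = sample.int(1e6, 1))
    recs <- generate_cohort(cfg, groups = "healthy")
    pe_cz <- function(rec) {
      vapply(segment_epochs(rec), function(ep) {
        th <- bandpass(ep$data, 4, 8, fs = 300)
        permutation_entropy(th[10, ], pe_spec())
      }, 0)
    }
    t.test(pe_cz(recs[[1]]), pe_cz(recs[[2]]))$p.value
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a positive theta complexity shift raises CPT theta entropy", {
  set.seed(105)
  eff <- effect_spec("theta", complexity_shift = 0.7,
                     affected_channels = c("Cz", "Fz", "Pz"))
  cfg <- cohort_config(n_subjects_per_group = 8,
                       epochs_per_condition = c(baseline = 2, cpt = 2),
                       effect = eff, seed = 106)
  recs <- generate_cohort(cfg, groups = "healthy")
  pe_mean <- function(rec) {
    mean(vapply(segment_epochs(rec), function(ep) {
      th <- bandpass(ep$data, 4, 8, fs = 300)
      mean(apply(th[c(5, 10, 15), ], 1, permutation_entropy, pe_spec()))
    }, 0))
  }
  base <- vapply(Filter(function(r) r$condition == "baseline", recs),
                 pe_mean, 0)
  cpt <- vapply(Filter(function(r) r$condition == "cpt", recs), pe_mean, 0)
  expect_lt(t.test(cpt, base, alternative = "greater")$p.value, 0.01)
})

test_that("the injected lead/lag gradient shows in the dPLI direction", {
  set.seed(107)
  # single generator with a dominant gradient: anterior channels lead
  cfg <- cohort_config(n_subjects_per_group = 1,
                       epochs_per_condition = c(baseline = 2, cpt = 1),
                       n_generators = 1, lag_jitter = 0.02,
                       shared_frac = 0.8, base_noise_mix = 0.1,
                       seed = 108)
  recs <- generate_cohort(cfg, groups = "healthy")
  ep <- segment_epochs(recs[[1]])[[1]]
  th <- bandpass(ep$data, 4, 8, fs = 300)
  D <- dpli(th)
  # generator phase is cos(phase - lag_c) with lag growing by channel
  # index: larger-lag (posterior) channels lead in phase
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  agree <- mean(ifelse(pairs[, 2] > pairs[, 1],
                       D[pairs] < 0.5, D[pairs] > 0.5))
  expect_true(agree >= 0.95 || agree <= 0.05)
})
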