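test_that("computed Slepian tapers match independently computed reference values", {
  tap <- dpss_tapers(64, nw = 2, k = 3)
  # frozen from an independent DPSS implementation (tridiagonal eigenvalue
  # route), first five samples of each taper at N = 64, NW = 2, K = 3
  ref <- matrix(c(0.0042298865, 0.0239774322, 0.0837576173,
                  0.0064220156, 0.0320850428, 0.0988737757,
                  0.0091032990, 0.0410997585, 0.1137199565,
                  0.0123110501, 0.0509394359, 0.1279317069,
                  0.0160769258, 0.0614954170, 0.1411416343),
                nrow = 5, byrow = TRUE)
  expect_equal(tap[1:5, ], ref, tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormality
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("multitaper spectrum localizes tones and scales quadratically", {
  s <- sine_epoch(10)
  ps <- multitaper_psd(s, fs = 300)
  expect_equal(ps$frequencies[which.max(ps$power[1, ])], 10)

  ps2 <- multitaper_psd(2 * s, fs = 300)
  expect_equal(ps2$power, 4 * ps$power, tolerance = 1e-10)

  expect_error(multitaper_psd(s, k = 5, nw = 2, fs = 300), "Slepian")
})

test_that("white-noise spectrum is flat and total power tracks variance", {
  set.seed(42)
  slopes <- replicate(20, {
    x <- matrix(rnorm(3000), 1)
    ps <- multitaper_psd(x, fs = 300)
    keep <- ps$frequencies > 1 & ps$frequencies < 140
    coef(lm(log(ps$power[1, keep]) ~ ps$frequencies[keep]))[2]
  })
  expect_lt(abs(mean(slopes)), 5e-4)

  # Parseval-style: integrated density approximates the signal variance
  set.seed(43)
  x <- matrix(rnorm(3000), 1)
  ps <- multitaper_psd(x, fs = 300)
  total <- sum(diff(ps$frequencies) *
                 (ps$power[1, -1] + ps$power[1, -length(ps$frequencies)]) / 2)
  expect_lt(abs(total / var(x[1, ]) - 1), 0.1)
})

test_that("band power integrates per band and tiles the total", {
  bands <- default_bands()
  s <- sine_epoch(10, nch = 19)
  ps <- multitaper_psd(s, fs = 300)
  bp <- sapply(seq_len(nrow(bands)), function(b) band_power(ps, bands[b, ]))
  expect_true(all(bp[, 3] >= 20 * bp[, -3]))  # alpha dominates

  expect_equal(unname(band_power(multitaper_psd(matrix(0, 1, 3000),
                                                fs = 300), bands[1, ])), 0)

  # adjacent trapezoids tile the 1-30 Hz integral exactly
  total <- band_power(ps, c(1, 30))
  expect_equal(rowSums(bp), total, tolerance = 1e-10)

  expect_error(band_power(ps, c(100, 200)), "outside")
})

test_that("peak frequency is the channel-averaged argmax with low tie-break", {
  bands <- default_bands()
  s6 <- sine_epoch(6, nch = 19)
  ps <- multitaper_psd(s6, fs = 300)
  expect_equal(peak_frequency(ps, band_by_name_test(bands, "theta")), 6)

  # two alpha tones, larger one wins
  t <- seq_len(3000) / 300
  s2 <- matrix(2 * sin(2 * pi * 9 * t) + 0.5 * sin(2 * pi * 11 * t), 1)
  ps2 <- multitaper_psd(s2, fs = 300)
  expect_equal(peak_frequency(ps2, band_by_name_test(bands, "alpha")), 9)

  # exactly flat spectrum -> lowest in-band frequency
  flat <- structure(list(frequencies = seq(0, 150, by = 0.1),
                         power = matrix(1, 2, 1501), k = 3, nw = 2,
                         fs = 300),
                    class = "power_spectrum")
  expect_equal(peak_frequency(flat, band_by_name_test(bands, "alpha")), 8)

  # peak always inside the band
  set.seed(7)
  x <- matrix(rnorm(3000), 1)
  psn <- multitaper_psd(x, fs = 300)
  for (b in seq_len(4)) {
    pk <- peak_frequency(psn, bands[b, ])
    expect_gte(pk, bands$low[b])
    expect_lte(pk, bands$high[b])
  }
})
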