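test_that("time-domain statistics behave on reference signals", {
  flat <- remove_dc_and_notch(eeg_segment(rep(5, 250), 250))
  tf <- time_features(flat)
  expect_equal(unname(tf["time_sd_raw"]), 0)
  expect_equal(unname(tf["time_max_raw"]), 0)

  # symmetric triangular wave: zero skewness
  tri <- eeg_segment(rep(c(seq(-50, 50, length.out = 25),
                           seq(50, -50, length.out = 25)), 5), 250)
  expect_lt(abs(time_features(tri)["time_skewness_raw"]), 1e-6)

  # Gaussian noise: Pearson kurtosis near 3, skewness near 0
  ks <- t(sapply(1:100, function(i) {
    set.seed(i)
    x <- rnorm(250)
    tf <- time_features(eeg_segment(x, 250), bands = eeg_bands(250)[0, ])
    tf[c("time_kurtosis_raw", "time_skewness_raw")]
  }))
  expect_lt(abs(mean(ks[, 1]) - 3), 0.5)
  expect_lt(abs(mean(ks[, 2])), 0.2)
})

test_that("Welch spectrum locates tones and conserves power", {
  p <- welch_psd(sine_segment(10))
  expect_true(all(p$psd >= 0))
  expect_lte(p$df, 1)
  expect_lt(abs(p$freq[which.max(p$psd)] - 10), p$df + 1e-9)
  # Parseval on a deterministic signal
  expect_lt(abs(sum(p$psd) * p$df / mean(sine_segment(10)$samples^2) - 1),
            0.05)
  # Parseval on noise, averaged over seeds
  ratio <- sapply(1:50, function(i) {
    set.seed(i)
    x <- rnorm(250)
    p <- welch_psd(x, 250)
    sum(p$psd) * p$df / mean(x^2)
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # zero in, zero out
  expect_true(all(welch_psd(eeg_segment(rep(0, 250), 250))$psd == 0))
})

test_that("white noise has roughly uniform band power per Hz", {
  bands <- eeg_bands(250)
  dens <- rowMeans(sapply(1:50, function(i) {
    set.seed(i)
    ff <- frequency_features(welch_psd(rnorm(250), 250), bands)
    ff[paste0("pow_", bands$name)] / (bands$f_hi - bands$f_lo)
  }))
  expect_lt(max(dens) / min(dens), 1.3 / 0.7)
})

test_that("frequency features normalise and summarise correctly", {
  bands <- eeg_bands(250)
  ff <- frequency_features(welch_psd(noise_segment(3)), bands)
  expect_equal(unname(sum(ff[paste0("relpow_", bands$name)])), 1,
               tolerance = 1e-9)
  ff10 <- frequency_features(welch_psd(sine_segment(10)), bands)
  expect_gte(unname(ff10["relpow_alpha"]), 0.95)
  # white-noise flatness near 1 (averaged)
  fl <- mean(sapply(1:50, function(i) {
    set.seed(i)
    frequency_features(welch_psd(rnorm(250), 250), bands)["spec_flatness"]
  }))
  expect_gte(fl, 0.8)
  # all-zero PSD falls back to defined values
  zz <- frequency_features(welch_psd(eeg_segment(rep(0, 250), 250)), bands)
  expect_true(all(is.finite(zz)))
  expect_equal(unname(zz[paste0("relpow_", bands$name)]), rep(0, 5))
})

test_that("entropy features cover the reference cases", {
  # flat normalised PSD -> spectral entropy exactly 1
  p <- structure(list(freq = 0:125, psd = c(0, rep(2, 125)), df = 1),
                 class = "eeg_psd")
  ent <- entropy_features(noise_segment(4), psd = p)
  expect_equal(unname(ent["spectral_entropy"]), 1, tolerance = 1e-9)
  # concentrated spectrum of a pure tone
  expect_lte(entropy_features(sine_segment(10))["spectral_entropy"], 0.35)
  # constant segment: all entropies 0 (rank-1 embedding)
  flat <- eeg_segment(rep(3, 250), 250)
  expect_equal(unname(entropy_features(flat)), c(0, 0, 0))
})

test_that("features are deterministic and scale-covariant", {
  seg <- noise_segment(5)
  expect_identical(segment_features(seg), segment_features(seg))
  f1 <- segment_features(seg)
  seg2 <- eeg_segment(2 * seg$samples, 250)
  f2 <- segment_features(seg2)
  expect_equal(unname(f2["time_sd_raw"] / f1["time_sd_raw"]), 2,
               tolerance = 1e-9)
  expect_equal(unname(f2["time_max_raw"] / f1["time_max_raw"]), 2,
               tolerance = 1e-9)
  for (nm in c("time_skewness_raw", "time_kurtosis_raw",
               "spectral_entropy", "relpow_alpha", "relpow_delta",
               "spec_flatness", "gamma_ratio"))
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-6)
})

test_that("no feature is NaN or Inf on degenerate segments", {
  zero <- eeg_segment(rep(0, 250), 250)
  const <- eeg_segment(rep(42, 250), 250)
  spike <- eeg_segment(c(rep(0, 249), 350), 250)
  sat <- eeg_segment(rep(c(-300, 300), 125), 250)
  for (seg in list(zero, const, spike, sat))
    expect_true(all(is.finite(segment_features(seg))),
                info = "degenerate segment produced non-finite feature")
})

test_that("standardization uses training statistics and guards zero variance", {
  set.seed(6)
  x <- cbind(a = rnorm(40, 5, 2), b = rnorm(40, -1, 0.1), c = rep(7, 40))
  params <- fit_standardization(x)
  z <- apply_standardization(x, params)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z[, 1:2], 2, sd) - 1)), 1e-9)
  expect_true(all(z[, "c"] == 0))
  # a test value equal to the training mean maps to 0
  probe <- matrix(params$mean, nrow = 1,
                  dimnames = list(NULL, colnames(x)))
  expect_equal(unname(apply_standardization(probe, params)[1, ]),
               c(0, 0, 0))
  bad <- matrix(rnorm(4), 2, dimnames = list(NULL, c("a", "zz")))
  expect_error(apply_standardization(bad, params), "match")
  expect_error(fit_standardization(x[1, , drop = FALSE]), "at least 2")
})
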