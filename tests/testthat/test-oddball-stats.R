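test_that("noise windows leave exactly 20 bins in both modes", {
  a <- with_seed(1, runif(1000, 0.5, 1.5))
  snr_idx <- noise_bins(a, 121, noise_window_spec("snr"))
  expect_equal(snr_idx, c(111:120, 122:131))
  z_idx <- noise_bins(a, 121, noise_window_spec("zscore"))
  expect_equal(length(z_idx), 20)
  expect_false(121 %in% z_idx)
  # adjacent bins are never part of the z window
  expect_false(any(c(120, 122) %in% z_idx))
  cand <- c(109:119, 123:133)
  expect_true(all(z_idx %in% cand))
  # the dropped two are the global extremes of the candidate window
  dropped <- setdiff(cand, z_idx)
  expect_equal(sort(a[dropped]),
               sort(c(min(a[cand]), max(a[cand]))))
})

test_that("a flat window drops exactly two bins, ties at lowest index", {
  a <- rep(1, 400)
  idx <- noise_bins(a, 200, noise_window_spec("zscore"))
  expect_equal(length(idx), 20)
  expect_equal(setdiff(c(188:198, 202:212), idx), c(188, 189))
})

test_that("windows too close to the spectrum edge raise an edge error", {
  a <- rep(1, 100)
  expect_error(noise_bins(a, 5, noise_window_spec("zscore")), "edge error")
  expect_error(noise_bins(a, 95, noise_window_spec("zscore")), "edge error")
  expect_silent(noise_bins(a, 13, noise_window_spec("zscore")))
})

test_that("bin statistics match hand-computed SNR, baseline and z", {
  # z window: 11 bins at 0.8 and 11 at 1.2; extremes drop one of each,
  # leaving ten and ten: mean 1, sample SD 0.205196, z = 4.8734
  a <- rep(1.0, 61)
  tb <- 31
  cand <- c((tb - 12):(tb - 2), (tb + 2):(tb + 12))
  a[cand] <- rep(c(0.8, 1.2), 11)
  a[tb] <- 2.0
  st <- bin_stats(a, target_bin = tb, df_hz = 0.1)
  expect_equal(st$corrected_amp, 1.0, tolerance = 1e-12)
  sd_hand <- sqrt(sum((rep(c(0.8, 1.2), 10) - 1)^2) / 19)
  expect_equal(st$z, 1.0 / sd_hand, tolerance = 1e-12)
  expect_equal(st$z, 4.8734, tolerance = 1e-4)

  # all-equal window: snr 2, corrected 1, z infinite with warning
  b <- rep(1.0, 61); b[tb] <- 2.0
  expect_warning(st2 <- bin_stats(b, target_bin = tb, df_hz = 0.1),
                 "noise SD is zero")
  expect_equal(st2$snr, 2.0)
  expect_equal(st2$corrected_amp, 1.0)
  expect_true(is.infinite(st2$z) && st2$z > 0)

  # target equal to the noise level: the null case
  c0 <- rep(1.0, 61)
  c0[cand] <- rep(c(0.9, 1.1), 11)
  c0[tb] <- 1.0
  st3 <- suppressWarnings(bin_stats(c0, target_bin = tb, df_hz = 0.1))
  expect_equal(st3$corrected_amp, 0, tolerance = 1e-12)
  expect_equal(st3$z, 0, tolerance = 1e-12)
})

test_that("bin statistics equal a brute-force recomputation on random spectra", {
  for (i in 1:100) {
    a <- with_seed(1000 + i, runif(80, 0.2, 2))
    tb <- with_seed(2000 + i, sample(14:66, 1))
    st <- bin_stats(a, target_bin = tb, df_hz = 0.1)
    oracle <- brute_bin_stats(a, tb)
    expect_equal(st$snr, oracle$snr, tolerance = 1e-12)
    expect_equal(st$corrected_amp, oracle$corrected, tolerance = 1e-12)
    expect_equal(st$z, oracle$z, tolerance = 1e-12)
  }
})

test_that("SNR spectra are 1 under flat/pure-noise input and track spikes", {
  sp <- amplitude_spectrum(fpvs_epoch(matrix(1, 1, 64), 64))
  sp$amps[] <- 1
  ss <- snr_spectrum(sp)
  inner <- ss$amps[1, !is.na(ss$amps[1, ])]
  expect_true(all(abs(inner - 1) < 1e-12))
  # white-noise baseline averages to ~1
  m <- vapply(1:20, function(seed) {
    v <- noise_amplitude_vector(2^13, 512, seed)
    s <- snr_spectrum(v)
    mean(s$amps[1, ], na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(m) - 1), 0.02)
  # a spike stands out as spike / local mean
  sp2 <- sp
  sp2$amps[] <- 1
  sp2$amps[1, 20] <- 6
  ss2 <- snr_spectrum(sp2)
  expect_equal(ss2$amps[1, 20], 6, tolerance = 1e-12)
  expect_error(snr_spectrum(sp, noise_window_spec("zscore")), "running mean")
})

test_that("candidate harmonics exclude base-rate multiples", {
  expect_equal(candidate_harmonics(2, 10, 8), c(2, 4, 6, 8))
  expect_equal(candidate_harmonics(2, 10, 20), c(2, 4, 6, 8, 12, 14, 16, 18))
  expect_equal(candidate_harmonics(10, 10, 40, exclude_base = FALSE),
               c(10, 20, 30, 40))
  # property: never a base multiple, for random settings
  for (i in 1:50) {
    f_base <- with_seed(i, sample(4:12, 1))
    h <- candidate_harmonics(2, f_base, 60)
    expect_false(any(h %% f_base == 0))
  }
})

test_that("group-level selection keeps exactly the injected harmonics", {
  e <- cosine_epoch(c(2, 4, 6), c(1, 0.8, 0.9), duration_s = 60, fs = 512)
  e$data <- e$data + matrix(with_seed(3, rnorm(ncol(e$data), sd = 0.05)),
                            1)
  sp <- amplitude_spectrum(e)
  sel <- select_significant_harmonics(sp, c(2, 4, 6, 8))
  expect_equal(sel, c(2, 4, 6))
  # everything injected, everything retained
  e2 <- cosine_epoch(c(2, 4, 6, 8), rep(1, 4), duration_s = 60, fs = 512)
  e2$data <- e2$data + matrix(with_seed(4, rnorm(ncol(e2$data), sd = 0.05)),
                              1)
  sel2 <- select_significant_harmonics(amplitude_spectrum(e2), c(2, 4, 6, 8))
  expect_equal(sel2, c(2, 4, 6, 8))
})

test_that("summed corrected amplitudes recover injected energy", {
  e <- cosine_epoch(c(2, 4, 6, 8), c(0.5, 0.3, 0.2, 0.1), duration_s = 60,
                    fs = 512)
  e$data <- e$data + matrix(with_seed(5, rnorm(ncol(e$data), sd = 0.02)), 1)
  sp <- amplitude_spectrum(e)
  hs <- sum_harmonics(sp, c(2, 4, 6, 8))
  expect_equal(hs$summed_corrected_amp, 1.1, tolerance = 0.01)
  expect_equal(sum(hs$per_harmonic$corrected_amp), hs$summed_corrected_amp)
  # single harmonic: the sum is that corrected amplitude
  hs1 <- sum_harmonics(sp, 2)
  expect_equal(hs1$summed_corrected_amp, hs1$per_harmonic$corrected_amp[1])
  expect_error(sum_harmonics(sp, numeric(0)), "empty harmonic")
})

test_that("pure-noise summed amplitudes average to zero over seeds", {
  sums <- vapply(1:40, function(seed) {
    v <- noise_amplitude_vector(2^13, 512, seed)
    sum_harmonics(v, c(2, 4, 6, 8))$summed_corrected_amp
  }, 0)
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums)), 2.5 * se + 1e-3)
})

test_that("summed-amplitude z matches its construction and the mean-z flag", {
  a <- rep(1.0, 200)
  bins_f <- c(2, 4, 6, 8)
  sp <- amplitude_spectrum(cosine_epoch(bins_f, c(2, 2, 2, 2),
                                        duration_s = 10, fs = 64))
  sp$amps[1, ] <- sp$amps[1, ] + 1  # lift the floor
  noisy <- with_seed(9, runif(length(sp$amps[1, ]), 0, 0.1))
  sp$amps[1, ] <- sp$amps[1, ] + noisy
  z1 <- summed_amplitude_z(sp, bins_f)
  # brute force: summed offsets with extremes dropped
  bins <- vapply(bins_f, function(f) bin_index(sp, f), 0L)
  offs <- c(-12:-2, 2:12)
  sn <- vapply(offs, function(o) sum(sp$amps[1, bins + o]), 0)
  sn <- sort(sn)[-c(1, length(sn))]
  expect_equal(z1$z, (sum(sp$amps[1, bins]) - mean(sn)) / sd(sn),
               tolerance = 1e-9)
  z2 <- summed_amplitude_z(sp, bins_f, method = "mean_z")
  zm <- mean(vapply(bins_f, function(f) bin_stats(sp, f)$z, 0))
  expect_equal(z2$z, zm, tolerance = 1e-12)
})
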