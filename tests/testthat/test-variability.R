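test_that("the analytical-variability power law evaluates and decreases in n", {
  m <- noise_model()
  expect_identical(analytical_variability(1, m), 0.0741)
  expect_equal(analytical_variability(10, m), 0.0741 * 10^-0.558)
  expect_equal(round(analytical_variability(10, m), 4), 0.0205)
  v <- analytical_variability(c(5, 10, 50), m)
  expect_true(all(diff(v) < 0))
  expect_error(analytical_variability(0, m), ">= 1")
  expect_error(noise_model(coeff = -1), "positive")
  expect_error(noise_model(exponent = 0.1), "negative")
})

test_that("series preparation interpolates interior gaps and detrends", {
  ser <- data.frame(age = seq(11.9, 11.801, by = -0.001) - 0.0005,
                    sst = rep(20, 100))
  prep <- prepare_series(ser)
  expect_equal(prep$anomaly, rep(0, 100))
  expect_equal(prep$n_interp, 0L)

  ser$sst[50] <- NA
  ser$sst[c(49, 51)] <- c(20, 22)
  prep2 <- prepare_series(ser)
  filled <- prep2$anomaly + prep2$trend
  expect_equal(filled[50], 21)
  expect_equal(prep2$n_interp, 1L)

  ser$sst[1] <- NA
  expect_error(prepare_series(ser), "leading/trailing")
  ser$sst[1] <- 20
  ser$sst[5:40] <- NA
  expect_error(prepare_series(ser), "missing exceeds")
})

test_that("the red-noise spectrum recovers a strong 120-yr line within one bin", {
  t <- 0:699
  x <- sin(2 * pi * t / 120)
  set.seed(2)
  spec <- redfit_spectrum(x + rnorm(700, 0, 0.05))
  pk <- spectrum_peak(spec, 60, 300)
  df <- diff(spec$freq[1:2])
  expect_false(is.na(pk))
  expect_lte(abs(1 / pk - 1 / 120), df + 1e-12)
  expect_true(all(spec$power >= 0))
  expect_lte(max(spec$freq), 0.5)
  expect_error(redfit_spectrum(rnorm(32)), "too short")
})

test_that("the AR(1) background coefficient is estimated consistently", {
  set.seed(31)
  phis <- replicate(10, {
    z <- as.numeric(arima.sim(list(ar = 0.7), n = 1000))
    redfit_spectrum(z)$phi
  })
  expect_equal(mean(phis), 0.7, tolerance = 0.05 / 0.7)
  expect_true(all(abs(phis - 0.7) < 0.1))
})

test_that("white noise exceeds the 95% false-alarm level about 5% of the time", {
  set.seed(17)
  frac <- replicate(120, {
    spec <- redfit_spectrum(rnorm(256))
    mean(spec$power[-1] > spec$fal95[-1])
  })
  expect_gt(mean(frac), 0.02)
  expect_lt(mean(frac), 0.09)
})

test_that("the Morlet wavelet localises a mid-record 40-yr burst", {
  expect_equal(max(morlet_wavelet(rep(0, 128) + 0)$power), 0)

  n <- 512
  x <- rep(0, n)
  burst <- 200:312
  x[burst] <- sin(2 * pi * (burst - 200) / 40)
  set.seed(4)
  w <- morlet_wavelet(x + rnorm(n, 0, 0.05))
  jrow <- which.min(abs(w$period - 40))
  # ridge period at peak power is ~40 yr
  peak <- which(w$power == max(w$power), arr.ind = TRUE)
  expect_equal(w$period[peak[1, 1]], 40, tolerance = 0.2)
  # inside the burst the 40-yr band is significant; far outside it is not
  expect_true(all(w$significant[jrow, 240:280]))
  expect_false(any(w$significant[jrow, c(40:80, 440:480)]))
  # cone of influence follows the e-folding closed form
  fourier_factor <- 4 * pi / (6 + sqrt(2 + 36))
  d <- pmin(0:(n - 1), (n - 1):0)
  expect_equal(w$coi, fourier_factor * d / sqrt(2))
  expect_error(morlet_wavelet(rnorm(32)), "too short")
})

test_that("wavelet global spectrum and redfit agree on a single sine's period", {
  t <- 0:699
  set.seed(5)
  x <- sin(2 * pi * t / 90) + rnorm(700, 0, 0.1)
  spec <- redfit_spectrum(x)
  wav <- morlet_wavelet(x)
  p_spec <- spectrum_peak(spec, 40, 200)
  p_wav <- wav$period[which.max(wav$global)]
  expect_equal(p_wav / p_spec, 1, tolerance = 0.15)
})

test_that("the 2-8-yr band-pass honours its gain contract", {
  t <- 0:499
  in_band <- sin(2 * pi * t / 5)
  out_band <- sin(2 * pi * t / 20)
  f_in <- bandpass_filter(in_band, 2, 8)
  f_out <- bandpass_filter(out_band, 2, 8)
  mid <- 100:400
  amp <- function(x) sqrt(2) * sd(x[mid])
  expect_gte(amp(f_in), 0.9)
  expect_lte(amp(f_out), 0.2)
  expect_equal(bandpass_filter(rep(0, 100), 2, 8), rep(0, 100))
  expect_error(bandpass_filter(rnorm(100), period_lo = 1.5), "Nyquist")
  # 3-yr and 7-yr sines also pass at >= 0.9
  expect_gte(amp(bandpass_filter(sin(2 * pi * t / 3), 2, 8)), 0.9)
  expect_gte(amp(bandpass_filter(sin(2 * pi * t / 7), 2, 8)), 0.9)
})

test_that("windowed variability reports per-block SDs with sine RMS A/sqrt(2)", {
  t <- 0:249
  x <- 0.8 * sin(2 * pi * t / 5)
  blocks <- windowed_variability(x, window = 25)
  expect_equal(nrow(blocks), 10L)
  expect_equal(blocks$sd, rep(0.8 / sqrt(2), 10), tolerance = 0.03)
  expect_equal(windowed_variability(rep(0, 60), 25)$sd, c(0, 0))
  # blocks partition the first floor(n/25)*25 samples
  b2 <- windowed_variability(rnorm(113), 25)
  expect_equal(sum(b2$end - b2$start + 1), 100)
  expect_error(windowed_variability(rnorm(100), window = 1), "at least 2")
})

test_that("noise correction subtracts the pooled analytical component", {
  calib <- calibration_config()
  # model tuned so the analytical mean is exactly 0.020 on the GC scale
  m <- noise_model(coeff = 0.020 / calib$gc_factor, exponent = -0.558)
  blocks <- data.frame(block = 1L, start = 1L, end = 25L, sd = 0.050,
                       n_years = 25L)
  out <- correct_variability(blocks, rep(1L, 25), m, calib)
  expect_equal(out$analytical_sd, 0.020)
  expect_equal(out$corrected_sd_c, (0.050 - 0.020) / 0.033)
  # observed equal to analytical -> corrected exactly 0
  blocks$sd <- 0.020
  expect_equal(correct_variability(blocks, rep(1L, 25), m, calib)$corrected_sd_c,
               0)
  # floor: observed below analytical never goes negative
  blocks$sd <- 0.001
  expect_equal(correct_variability(blocks, rep(1L, 25), m, calib)$corrected_sd,
               0)
  expect_error(correct_variability(blocks, c(NA, rep(1L, 24)), m, calib),
               "missing spot counts")
})

test_that("subtracting more analytical noise never raises the corrected SD", {
  set.seed(9)
  blocks <- data.frame(block = 1:4, start = c(1, 26, 51, 76),
                       end = c(25, 50, 75, 100),
                       sd = runif(4, 0.01, 0.05), n_years = 25)
  n_spots <- sample(10:60, 100, replace = TRUE)
  coefs <- seq(0.01, 0.12, length.out = 8)
  for (domain in c("sd", "variance")) {
    prev <- NULL
    for (cf in coefs) {
      cur <- correct_variability(blocks, n_spots, noise_model(coeff = cf),
                                 domain = domain)$corrected_sd
      if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
      prev <- cur
    }
  }
})

test_that("era-dependent interannual variability is recovered from simulation", {
  cfg <- default_scenario(seed = 13L)
  p <- sim_prepared(cfg)
  ann <- reconstruct_annual_sst(p$table, p$age_model,
                                age_breaks = seq(cfg$age_end, cfg$age_start,
                                                 0.001))
  prep <- prepare_series(ann, value = "u37_gc")
  filt <- bandpass_filter(prep$anomaly, 2, 8)
  blocks <- windowed_variability(filt, 25)
  blocks <- correct_variability(blocks, ann$n_spots, noise_model(),
                                calibration_config(), domain = "variance")
  mid_age <- vapply(seq_len(nrow(blocks)), function(b)
    mean(ann$age[blocks$start[b]:blocks$end[b]]), 0)
  old <- mid_age > cfg$interannual_change_age
  est_old <- mean(blocks$corrected_sd_c[old])
  est_young <- mean(blocks$corrected_sd_c[!old])
  expect_equal(est_old, cfg$interannual_sd[1], tolerance = 0.2)
  expect_equal(est_young, cfg$interannual_sd[2], tolerance = 0.2)
})

test_that("two-group comparisons behave as expected", {
  same <- c(1, 2, 3, 4, 5)
  mw <- compare_groups(same, same, test = "mann_whitney")
  expect_gt(mw$p_value, 0.9)
  set.seed(23)
  strong <- vapply(1:20, function(i) {
    compare_groups(rnorm(50), rnorm(50, 2), test = "t")$p_value
  }, 0)
  expect_true(all(strong < 0.001))
  a <- c(3, 4, 5, 6); b <- c(1, 2, 2, 3)
  expect_gt(compare_groups(a, b, test = "t")$statistic, 0)
  expect_lt(compare_groups(b, a, test = "t")$statistic, 0)
  deg <- compare_groups(c(1, 1, 1), c(1, 1, 1), test = "t")
  expect_true(deg$degenerate)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
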