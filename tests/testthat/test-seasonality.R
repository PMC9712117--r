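test_that("elemental profiles bin by exactly 5 GS units and locate the peaks", {
  cfg <- quiet_scenario(seed = 14L)
  p <- sim_prepared(cfg)
  prof <- elemental_gs_profile(p$table)
  expect_true(all(prof$bin_hi - prof$bin_lo == 5))
  expect_equal(sum(prof$n), sum(!p$table$spots$background))
  eligible <- prof$n >= 25
  for (el in c("fe", "ti", "ca")) {
    expect_lt(prof$bin_mid[eligible][which.max(prof[[el]][eligible])], 0)
  }
  expect_gt(prof$bin_mid[eligible][which.max(prof$si[eligible])], 0)
})

test_that("a flat elemental field yields a flat profile", {
  set.seed(15)
  n <- 2000
  tab <- compute_delta_gs(spot_table(
    make_spots(n, gs = runif(n, 100, 200),
               ca = runif(n, 90, 110), fe = runif(n, 90, 110),
               ti = runif(n, 90, 110), si = runif(n, 90, 110)),
    make_slices()))
  prof <- elemental_gs_profile(tab)
  busy <- prof$n >= 50
  expect_lt(diff(range(prof$ca[busy])) / mean(prof$ca[busy]), 0.1)
})

test_that("threshold search equals an independent brute-force enumeration", {
  for (seed in 1:8) {
    tab <- random_season_table(seed)
    prof <- elemental_gs_profile(tab)
    oracle <- brute_force_threshold(tab$spots)
    got <- tryCatch(
      find_season_threshold(tab, prof, min_bin_count = 1),
      error = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, oracle$threshold)
      expect_equal(got$fallback_used, oracle$fallback_used)
    }
  }
})

test_that("a clean bimodal table is split between the modes, dark side warmer", {
  tab <- random_season_table(99, n = 400)
  prof <- elemental_gs_profile(tab)
  thr <- find_season_threshold(tab, prof)
  expect_gt(thr$threshold, -30)
  expect_lt(thr$threshold, 30)
  expect_gt(thr$sst_dark, thr$sst_light)
  expect_equal(thr$frac_dark + thr$frac_light, 1)
  # season label sanity: non-upwelling (dark) spots are darker on average
  dark <- tab$spots$delta_gs < thr$threshold
  expect_lt(mean(tab$spots$gs[dark]), mean(tab$spots$gs[!dark]))
})

test_that("the 15% fallback engages when elemental constraints pinch the split", {
  n <- 300
  # 80% of spots dark at one exact greyscale: the slice median sits on the
  # dark mode, the dark elemental peak bin ends at +5, and any admissible
  # cut leaves only the 20% light spots on one side -> 15% fallback
  dark <- seq_len(n) <= 240
  gs <- ifelse(dark, 130, 175)
  u <- ifelse(dark, 0.73, 0.67)
  tab <- compute_delta_gs(spot_table(
    make_spots(n, gs = gs, i372 = 100 * u, i373 = 100 * (1 - u),
               ca = ifelse(dark, 200, 100), fe = ifelse(dark, 200, 100),
               ti = ifelse(dark, 200, 100), si = ifelse(dark, 100, 200)),
    make_slices()))
  prof <- elemental_gs_profile(tab)
  thr <- find_season_threshold(tab, prof, min_bin_count = 1)
  expect_true(thr$fallback_used)
  expect_gte(min(thr$frac_dark, thr$frac_light), 0.15)
  oracle <- brute_force_threshold(tab$spots)
  expect_equal(thr$threshold, oracle$threshold)
  expect_true(oracle$fallback_used)
})

test_that("zero true seasonality gives a near-zero SST split", {
  cfg <- quiet_scenario(seasonality_fn = function(age) 0 * age, seed = 16L,
                        age_start = 11.35)
  p <- sim_prepared(cfg)
  prof <- elemental_gs_profile(p$table)
  thr <- find_season_threshold(p$qc, prof)
  expect_lt(abs(thr$sst_diff), 0.2)
})

test_that("5-yr seasonal records recover a stepped seasonality and honour QC", {
  cfg <- default_scenario(seed = 18L)
  p <- sim_prepared(cfg)
  thrs <- season_thresholds_by_slice(p$table, p$qc)
  ser <- seasonal_sst_series(p$qc, thrs, p$ages)
  post <- ser$seasonality[ser$age_mid <= 11.64 & !is.na(ser$seasonality)]
  pre <- ser$seasonality[ser$age_mid > 11.64 & !is.na(ser$seasonality)]
  expect_equal(mean(post), 1.8, tolerance = 0.3 / 1.8)
  expect_equal(mean(pre), 0.8, tolerance = 0.3 / 0.8)
  # a season with fewer than min_spots in a bin is missing there
  few <- seasonal_sst_series(p$qc, thrs, p$ages, min_spots = 1e6)
  expect_true(all(is.na(few$seasonality)))
})

test_that("the seasonality increase is robust to threshold perturbation", {
  cfg <- default_scenario(seed = 19L)
  p <- sim_prepared(cfg)
  thrs <- season_thresholds_by_slice(p$table, p$qc)
  for (shift in c(-3, 3)) {
    tsh <- thrs
    tsh$threshold <- tsh$threshold + shift
    ser <- seasonal_sst_series(p$qc, tsh, p$ages)
    ok <- !is.na(ser$seasonality)
    before <- ser$seasonality[ok & ser$age_mid > 11.64]
    after <- ser$seasonality[ok & ser$age_mid <= 11.64]
    expect_gt(mean(after) - mean(before), 0)
    mw <- compare_groups(before, after, test = "mann_whitney")
    expect_lt(mw$p_value, 0.01)
  }
})

test_that("ramp fitting is exact on noiseless in-class inputs", {
  age <- seq(11.9, 11.2, by = -0.005)
  # step at 11.64: start = end = the change point
  y_step <- ifelse(age >= 11.64, 0.8, 1.8)
  f <- fit_ramp(age, y_step)
  expect_equal(f$level_before, 0.8)
  expect_equal(f$level_after, 1.8)
  expect_lte(abs(f$t_mid - 11.64), 0.005)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  # genuine ramp between grid points 11.75 and 11.60
  ts <- 11.75; te <- 11.60
  w <- pmin(pmax((age - te) / (ts - te), 0), 1)
  y_ramp <- 1.8 + (0.6 - 1.8) * w
  f2 <- fit_ramp(age, y_ramp)
  expect_equal(f2$t_start, ts)
  expect_equal(f2$t_end, te)
  expect_equal(f2$level_before, 0.6)
  expect_equal(f2$level_after, 1.8)
})

test_that("constrained ramps keep their breakpoints inside the stated intervals", {
  set.seed(20)
  age <- seq(11.9, 11.2, by = -0.005)
  y <- ifelse(age >= 11.64, 0.8, 1.8) + rnorm(length(age), 0, 0.2)
  f <- fit_ramp(age, y, constrain_start = c(11.725, 11.8),
                constrain_end = c(11.6, 11.675))
  expect_true(f$constrained)
  expect_gte(f$t_start, 11.725); expect_lte(f$t_start, 11.8)
  expect_gte(f$t_end, 11.6); expect_lte(f$t_end, 11.675)
  expect_error(fit_ramp(age, y, constrain_start = c(12.5, 12.6)),
               "no grid points")
  # negative values are excluded before fitting
  y2 <- c(-5, y[-1])
  f2 <- fit_ramp(age, y2)
  expect_equal(f2$n_used, length(age) - 1L)
})

test_that("ramp parameters are recovered across seeds", {
  fits <- lapply(1:20, function(seed) {
    cfg <- default_scenario(seed = 100L + seed)
    p <- sim_prepared(cfg)
    thrs <- season_thresholds_by_slice(p$table, p$qc)
    ser <- seasonal_sst_series(p$qc, thrs, p$ages)
    fit_ramp(ser$age_mid, ser$seasonality)
  })
  mids <- vapply(fits, `[[`, 0, "t_mid")
  before <- vapply(fits, `[[`, 0, "level_before")
  after <- vapply(fits, `[[`, 0, "level_after")
  expect_lte(abs(median(mids) - 11.64), 0.015)
  expect_lte(abs(median(before) - 0.8), 0.2)
  expect_lte(abs(median(after) - 1.8), 0.2)
})

test_that("the sinusoid conversion maps season-mean differences to amplitudes", {
  expect_equal(amplitude_from_seasonality(0), 0)
  expect_equal(amplitude_from_seasonality(1.0), pi / 2)
  expect_equal(round(amplitude_from_seasonality(1.2), 3), 1.885)
  expect_error(amplitude_from_seasonality(-0.1), "non-negative")
  # closed form check against numerical half-cycle means of a sinusoid
  a <- 1.3                                   # half-amplitude
  th <- seq(0, pi, length.out = 20001)
  half_mean <- mean(a * sin(th))
  d <- 2 * half_mean                         # warm minus cold half-cycle mean
  expect_equal(amplitude_from_seasonality(d), 2 * a, tolerance = 1e-4)
})
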