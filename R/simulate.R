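#' Scenario configuration for the varved-sediment MSI simulator
#'
#' Bundles every knob of the forward model.  Defaults describe a
#' Cariaco-like Younger Dryas to early Holocene section: ages 11.9 to
#' 11.2 kyr b2k, sedimentation rate dropping from 1.4 to 0.5 mm/yr at the
#' reflectance midpoint 11.673 kyr b2k, constant true annual-mean SST of
#' 23.8 degC, a true seasonal (non-upwelling minus upwelling) SST
#' difference stepping from 0.8 to 1.8 degC at 11.64 kyr b2k, centennial
#' (120-yr) and multidecadal (42-yr) sinusoidal anomalies, an AR(1)
#' interannual anomaly whose 2-8-yr band standard deviation is set per era,
#' and a per-spot proxy noise law whose pooled precision follows the
#' power-law analytical-variability model (see [analytical_variability()]).
#'
#' @param age_start,age_end record span in kyr b2k (`age_start` is older,
#'   hence larger).
#' @param transition_age age of the sedimentation-rate change, kyr b2k.
#' @param sed_rate_old,sed_rate_young sedimentation rates (mm/yr) before and
#'   after `transition_age`; annual varve thickness in mm equals the rate.
#' @param mean_sst true annual-mean SST, degC.
#' @param seasonality_fn function of age (kyr b2k) returning the true
#'   non-upwelling-minus-upwelling SST difference in degC.  Default: step
#'   from 0.8 (older) to 1.8 degC at 11.64 kyr b2k.
#' @param cycle_periods,cycle_amplitudes sinusoidal anomaly periods (yr) and
#'   amplitudes (degC).
#' @param interannual_sd 2-8-yr band standard deviation (degC) of the AR(1)
#'   anomaly, length-2 vector `c(old, young)` split at
#'   `interannual_change_age`.
#' @param interannual_change_age era boundary for `interannual_sd`, kyr b2k.
#' @param ar1_phi lag-1 autoregressive coefficient of the interannual
#'   anomaly.
#' @param white_sd additional white-noise SD on the annual mean, degC.
#' @param noise_coeff per-spot proxy noise SD (U37K' units, MSI scale);
#'   additive Gaussian on the single-spot ratio, so pooling n spots of
#'   equal intensity scales the SD by about n^-0.5.
#' @param noise_exp exponent of the fitted analytical-variability law used
#'   by the correction stage (not forced in the generator).
#' @param gc_factor,calib_slope,calib_intercept proxy calibration shared
#'   with the reconstruction: `u_gc = calib_slope * SST + calib_intercept`,
#'   `u_msi = u_gc / gc_factor`.
#' @param season_abundance_ratio mean alkenone intensity ratio
#'   non-upwelling / upwelling.
#' @param detect_prob probability that a spot yields detectable amounts of
#'   both alkenones.
#' @param spot_pitch_um raster pitch, micrometres.
#' @param slice_len_mm,slice_width_mm slice geometry (50 x 4 mm at 100 um
#'   pitch gives the canonical 20,000 spots per 5-cm slice).
#' @param depth_start_cm composite depth (cm bsf) of the top of the
#'   youngest slice.
#' @param dark_fraction fraction of each varve's thickness occupied by the
#'   dark (non-upwelling) lamina.
#' @param gs_dark_mean,gs_light_mean,gs_sd greyscale model per lamina type.
#' @param elem_base,elem_contrast,elem_sdlog lognormal elemental-intensity
#'   model: Fe, Ti, Ca are `elem_contrast`-fold enriched in dark laminae,
#'   Si in light laminae.
#' @param intensity_meanlog,intensity_sdlog lognormal total alkenone
#'   intensity per detected spot (before the seasonal abundance factor).
#' @param sn_unit intensity corresponding to signal-to-noise 1.
#' @param background_gs mean greyscale of sediment-free (background) raster
#'   positions beyond the base of the simulated record.
#' @param seed integer seed; identical config and seed give a byte-identical
#'   dataset.
#' @return object of class `scenario_config` (a list).
#' @export
scenario_config <- function(age_start = 11.9, age_end = 11.2,
                            transition_age = 11.673,
                            sed_rate_old = 1.4, sed_rate_young = 0.5,
                            mean_sst = 23.8,
                            seasonality_fn = function(age)
                              ifelse(age > 11.64, 0.8, 1.8),
                            cycle_periods = c(120, 42),
                            cycle_amplitudes = c(0.3, 0.2),
                            interannual_sd = c(0.15, 0.35),
                            interannual_change_age = 11.66,
                            ar1_phi = 0.5, white_sd = 0.1,
                            noise_coeff = 0.0741, noise_exp = -0.558,
                            gc_factor = 1.194,
                            calib_slope = 0.033, calib_intercept = 0.044,
                            season_abundance_ratio = 1.5,
                            detect_prob = 0.7,
                            spot_pitch_um = 100,
                            slice_len_mm = 50, slice_width_mm = 4,
                            depth_start_cm = 480,
                            dark_fraction = 0.5,
                            gs_dark_mean = 130, gs_light_mean = 170,
                            gs_sd = 5,
                            elem_base = 100, elem_contrast = 2,
                            elem_sdlog = 0.3,
                            intensity_meanlog = log(100),
                            intensity_sdlog = 0.3,
                            sn_unit = 1,
                            background_gs = 5,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$age_start <= cfg$age_end) {
    stop("config error: age_start must be older (larger) than age_end",
         call. = FALSE)
  }
  if (cfg$sed_rate_old <= 0 || cfg$sed_rate_young <= 0) {
    stop("config error: sedimentation rates must be positive", call. = FALSE)
  }
  if (cfg$detect_prob < 0 || cfg$detect_prob > 1) {
    stop("config error: detect_prob must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$calib_slope <= 0) {
    stop("config error: calib_slope must be positive", call. = FALSE)
  }
  if (any(cfg$cycle_periods <= 0)) {
    stop("config error: cycle periods must be positive", call. = FALSE)
  }
  if (any(cfg$interannual_sd < 0) || cfg$white_sd < 0) {
    stop("config error: standard deviations must be non-negative",
         call. = FALSE)
  }
  if (length(cfg$cycle_periods) != length(cfg$cycle_amplitudes)) {
    stop("config error: cycle_periods and cycle_amplitudes lengths differ",
         call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

#' Simulate the annual ground truth
#'
#' Builds the per-year true SST decomposition and varve geometry for a
#' scenario.  The annual mean is `mean_sst` plus sinusoids at
#' `cycle_periods`, an AR(1) anomaly rescaled per era so that its 2-8-yr
#' band standard deviation equals `interannual_sd`, and white noise.
#' Seasonal truths sit symmetrically at plus/minus half the seasonal
#' difference around the annual mean, so the non-upwelling minus upwelling
#' difference equals `seasonality_fn(age)` exactly.  Varves are stacked
#' from the youngest year at depth 0 downwards with thickness equal to the
#' era's sedimentation rate.
#'
#' @param config a [scenario_config()].
#' @return object of class `truth_record`: a data frame with one row per
#'   year, oldest first (ages strictly decreasing with row number), with
#'   columns `age`, `sst_annual`, `sst_nonupw`,
#'   `sst_upw`, `seasonality`, `depth_top_mm`, `depth_bot_mm`,
#'   `lamina_boundary_mm`, and the anomaly decomposition `cyclic`, `ar1`,
#'   `white`.  The scenario is attached as attribute `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  dy <- 0.001                                # 1 yr in kyr
  n <- round((config$age_start - config$age_end) / dy)
  if (n < 1L) stop("config error: record shorter than one year", call. = FALSE)
  j <- seq_len(n)                            # 1 = oldest year
  age <- config$age_start - (j - 0.5) * dy   # varve midpoint age
  t_yr <- j - 1                              # forward time in years

  cyclic <- rep(0, n)
  for (k in seq_along(config$cycle_periods)) {
    cyclic <- cyclic + config$cycle_amplitudes[k] *
      sin(2 * pi * t_yr / config$cycle_periods[k])
  }

  # AR(1) anomaly, rescaled per era to the target 2-8-yr band SD
  ar1 <- rep(0, n)
  if (any(config$interannual_sd > 0) && n >= 16L) {
    z <- if (config$ar1_phi != 0) {
      as.numeric(stats::arima.sim(list(ar = config$ar1_phi), n = n))
    } else {
      stats::rnorm(n)
    }
    zb <- bandpass_filter(z, period_lo = 2, period_hi = 8)
    era_old <- age > config$interannual_change_age
    for (e in list(c(TRUE, 1L), c(FALSE, 2L))) {
      sel <- era_old == e[1L]
      if (sum(sel) < 2L) next
      target <- config$interannual_sd[e[2L]]
      s <- stats::sd(zb[sel])
      ar1[sel] <- if (s > 0) z[sel] * target / s else 0
    }
  }
  white <- if (config$white_sd > 0) stats::rnorm(n, 0, config$white_sd) else rep(0, n)

  sst_annual <- config$mean_sst + cyclic + ar1 + white
  seasonality <- config$seasonality_fn(age)
  sst_nonupw <- sst_annual + seasonality / 2
  sst_upw <- sst_annual - seasonality / 2

  # varve stack: youngest year at depth 0, thickness = era sedimentation rate
  thick <- ifelse(age > config$transition_age,
                  config$sed_rate_old, config$sed_rate_young)
  # cumulative depth from the top: youngest (j = n) first
  bot_rev <- cumsum(rev(thick))              # bottoms, youngest first
  depth_bot <- rev(bot_rev)
  depth_top <- depth_bot - thick

  out <- data.frame(age = age,
                    sst_annual = sst_annual,
                    sst_nonupw = sst_nonupw,
                    sst_upw = sst_upw,
                    seasonality = seasonality,
                    depth_top_mm = depth_top,
                    depth_bot_mm = depth_bot,
                    lamina_boundary_mm = depth_top +
                      config$dark_fraction * thick,
                    cyclic = cyclic, ar1 = ar1, white = white)
  out <- out[order(out$age, decreasing = TRUE), ]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("truth_record", "data.frame")
  out
}

#' Simulate an MSI spot-table dataset from a ground truth
#'
#' Rasters a stack of 5-cm slices at the configured pitch; assigns each
#' raster position to the varve and lamina containing its depth; draws
#' greyscale and elemental intensities per lamina type (Fe, Ti, Ca enriched
#' in the dark, non-upwelling lamina; Si in the light, upwelling lamina);
#' and, for spots in which both alkenones are detected, draws a lognormal
#' total alkenone intensity (larger in the non-upwelling season by
#' `season_abundance_ratio`) and splits it by the noisy proxy ratio
#' `r = clamp(u_true + N(0, noise_coeff), 0, 1)` with
#' `u_true = (calib_slope * SST_season + calib_intercept) / gc_factor`.
#' Raster positions beyond the base of the simulated record are imaged as
#' black background.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [scenario_config()].
#' @return a [spot_table()].
#' @export
simulate_dataset <- function(truth, config) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  pitch_mm <- config$spot_pitch_um / 1000
  rows_per_slice <- round(config$slice_len_mm / pitch_mm)
  cols <- round(config$slice_width_mm / pitch_mm)
  total_depth <- max(truth$depth_bot_mm)
  if (config$slice_len_mm < min(truth$depth_bot_mm - truth$depth_top_mm)) {
    stop("config error: slice shorter than one varve", call. = FALSE)
  }
  n_slices <- ceiling(total_depth / config$slice_len_mm)

  slices <- data.frame(
    slice_id = sprintf("S%02d", seq_len(n_slices)),
    offset_cm_bsf = config$depth_start_cm +
      (seq_len(n_slices) - 1) * config$slice_len_mm / 10,
    length_mm = config$slice_len_mm,
    width_mm = config$slice_width_mm,
    stringsAsFactors = FALSE)

  # full raster, slice by slice
  slice_idx <- rep(seq_len(n_slices), each = rows_per_slice * cols)
  row_idx <- rep(rep(seq_len(rows_per_slice), each = cols), times = n_slices)
  col_idx <- rep(seq_len(cols), times = rows_per_slice * n_slices)
  depth_in_slice <- (row_idx - 0.5) * pitch_mm
  depth_global <- (slice_idx - 1) * config$slice_len_mm + depth_in_slice
  n_spots <- length(depth_global)

  # varve assignment: truth is oldest-first; boundaries increase with depth
  # when taken youngest-first
  ord <- order(truth$depth_top_mm)           # youngest (shallowest) first
  tops <- truth$depth_top_mm[ord]
  year_of <- findInterval(depth_global, c(tops, total_depth),
                          rightmost.closed = TRUE)
  in_sediment <- year_of >= 1L & depth_global < total_depth
  year_row <- ifelse(in_sediment, ord[pmax(year_of, 1L)], NA_integer_)
  dark <- rep(FALSE, n_spots)
  dark[in_sediment] <-
    depth_global[in_sediment] < truth$lamina_boundary_mm[year_row[in_sediment]]

  gs <- numeric(n_spots)
  gs[in_sediment] <- stats::rnorm(sum(in_sediment),
                                  ifelse(dark[in_sediment],
                                         config$gs_dark_mean,
                                         config$gs_light_mean),
                                  config$gs_sd)
  gs[!in_sediment] <- stats::rnorm(sum(!in_sediment), config$background_gs, 2)
  gs <- pmin(pmax(gs, 0), 255)

  draw_elem <- function(enriched_in_dark) {
    m <- ifelse(xor(dark, !enriched_in_dark),  # dark & enriched, or light & light-enriched
                log(config$elem_base * config$elem_contrast),
                log(config$elem_base))
    v <- stats::rlnorm(n_spots, m, config$elem_sdlog)
    v[!in_sediment] <- 0
    v
  }
  ca <- draw_elem(TRUE); fe <- draw_elem(TRUE); ti <- draw_elem(TRUE)
  si <- draw_elem(FALSE)

  detected <- in_sediment &
    stats::runif(n_spots) < config$detect_prob
  nd <- sum(detected)
  i372 <- numeric(n_spots); i373 <- numeric(n_spots)
  if (nd > 0L) {
    sst_season <- ifelse(dark[detected],
                         truth$sst_nonupw[year_row[detected]],
                         truth$sst_upw[year_row[detected]])
    u_true <- (config$calib_slope * sst_season + config$calib_intercept) /
      config$gc_factor
    r <- u_true + stats::rnorm(nd, 0, config$noise_coeff)
    r <- pmin(pmax(r, 0), 1)
    total <- stats::rlnorm(nd, config$intensity_meanlog +
                             ifelse(dark[detected],
                                    log(config$season_abundance_ratio), 0),
                           config$intensity_sdlog)
    i372[detected] <- total * r
    i373[detected] <- total * (1 - r)
  }

  spots <- data.frame(
    spot_id = seq_len(n_spots),
    slice_id = slices$slice_id[slice_idx],
    x_um = (col_idx - 0.5) * config$spot_pitch_um,
    y_um = (row_idx - 0.5) * config$spot_pitch_um,
    depth_mm = depth_in_slice,
    gs = gs, ca = ca, fe = fe, ti = ti, si = si,
    i372 = i372, i373 = i373,
    sn372 = i372 / config$sn_unit,
    sn373 = i373 / config$sn_unit,
    stringsAsFactors = FALSE)
  spot_table(spots, slices)
}

#' Exact age-depth model for a simulated truth
#'
#' Control points at the record top, base and every change in varve
#' thickness, so that piecewise-linear interpolation reproduces the
#' simulated depth-age relation exactly.
#'
#' @param truth a [simulate_truth()] result.
#' @return an [age_depth_model()].
#' @export
age_model_from_truth <- function(truth) {
  stopifnot(inherits(truth, "truth_record"))
  config <- attr(truth, "config")
  dy <- 0.001
  ord <- order(truth$depth_top_mm)           # youngest first
  tops <- truth$depth_top_mm[ord]
  bots <- truth$depth_bot_mm[ord]
  thick <- bots - tops
  # boundary above varve k (youngest-first ordering) has age age_end + (k-1)yr
  b_depth <- c(tops, bots[length(bots)])
  b_age <- config$age_end + (seq_along(b_depth) - 1) * dy
  keep <- c(TRUE, diff(thick) != 0, TRUE)    # top, rate changes, base
  age_depth_model(config$depth_start_cm + b_depth[keep] / 10, b_age[keep])
}
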