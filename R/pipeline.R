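#' Pipeline run configuration
#'
#' Bundles scenario, calibration, noise model, QC thresholds and the
#' analysis ages driving [run_full_pipeline()].
#'
#' @param scenario a [scenario_config()] (used when simulating).
#' @param calib a [calibration_config()].
#' @param noise a [noise_model()].
#' @param sn_min,min_spots spot QC thresholds.
#' @param background_gs_max background greyscale exclusion threshold.
#' @param bin_years seasonal-record bin width, years.
#' @param transition_mid reflectance midpoint of the YD-Holocene
#'   transition, kyr b2k (default 11.673); centre of the windowed-mean
#'   comparison.
#' @param transition_halfwidth_yr half-width of the windowed-mean
#'   comparison, years (default 200).
#' @param variability_split era boundary for the variability comparison,
#'   kyr b2k (default 11.66).
#' @param variability_window block length for windowed variability, years.
#' @param ramp_start_interval,ramp_end_interval constraint intervals
#'   (kyr b2k) for the constrained ramp fit.
#' @param variability_domain `"sd"` or `"variance"`, see
#'   [correct_variability()].
#' @param seed integer master seed; overrides `scenario$seed`.
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            calib = calibration_config(),
                            noise = noise_model(),
                            sn_min = 3, min_spots = 10,
                            background_gs_max = 30,
                            bin_years = 5,
                            transition_mid = 11.673,
                            transition_halfwidth_yr = 200,
                            variability_split = 11.66,
                            variability_window = 25,
                            ramp_start_interval = c(11.725, 11.8),
                            ramp_end_interval = c(11.6, 11.675),
                            variability_domain = "sd",
                            seed = NULL) {
  cfg <- as.list(environment())
  if (!is.null(seed)) cfg$scenario$seed <- as.integer(seed)
  cfg$seed <- cfg$scenario$seed
  structure(cfg, class = "run_config")
}

provenance_header <- function(config) {
  hash <- sum(utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                     "scenario")]),
                              collapse = ""))) %% 1000000L
  sprintf("# varveSST %s | seed %d | config checksum %06d",
          as.character(utils::packageVersion("varveSST")),
          config$seed, hash)
}

write_with_header <- function(df, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full simulate-reconstruct-analyse pipeline
#'
#' Chains the forward simulator, the annual SST reconstruction, the
#' greyscale season deconvolution with ramp fitting, and the
#' interannual-variability analysis with analytical-noise correction,
#' under a single configuration and seed, and (when the truth is
#' simulated) reports recovered-versus-true quantities.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, CSV/JSON outputs with
#'   provenance headers are written there.
#' @param verbose print stage progress to stderr.
#' @return list with elements `truth`, `table`, `age_model`, `annual`
#'   (annual series incl. smoothed SST), `window_means`, `thresholds`,
#'   `seasonal`, `ramp_unconstrained`, `ramp_constrained`,
#'   `seasonality_test`, `amplitude`, `variability` (blocks),
#'   `variability_test`, `spectrum`, `wavelet`, `recovery`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[varveSST] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("simulate")
  truth <- stage("simulate", simulate_truth(config$scenario))
  table <- stage("simulate", simulate_dataset(truth, config$scenario))
  age_model <- age_model_from_truth(truth)
  table <- stage("normalise",
                 compute_delta_gs(table, config$background_gs_max))

  say("reconstruct")
  qc <- suppressMessages(qc_filter_spots(table, sn_min = config$sn_min))
  breaks <- seq(config$scenario$age_end, config$scenario$age_start,
                by = 0.001)
  annual <- stage("reconstruct", {
    ages <- depth_to_age(age_model, spot_composite_depth(qc))
    ann <- pool_annual(qc, ages, age_breaks = breaks,
                       min_spots = config$min_spots)
    ann$u37_msi <- NA_real_
    ok <- !ann$missing
    ann$u37_msi[ok] <- compute_uk37(ann$i372_sum[ok], ann$i373_sum[ok])
    ann$u37_gc <- as.numeric(suppressWarnings(
      to_gc_equivalent(ann$u37_msi, config$calib)))
    ann$sst <- calibrate_sst(ann$u37_gc, config$calib)
    ann$sst_smooth <- smooth_gaussian(ann$sst, 15)
    ann
  })
  hw <- config$transition_halfwidth_yr * 0.001
  window_means <- window_stats(annual, list(
    c(config$transition_mid, config$transition_mid + hw),   # older side
    c(config$transition_mid - hw, config$transition_mid)))  # younger side

  say("seasonality")
  seas <- stage("seasonality", {
    thresholds <- season_thresholds_by_slice(table, qc, config$calib)
    ages <- depth_to_age(age_model, spot_composite_depth(qc))
    series <- seasonal_sst_series(qc, thresholds, ages,
                                  bin_years = config$bin_years,
                                  min_spots = config$min_spots,
                                  calib = config$calib)
    ru <- fit_ramp(series$age_mid, series$seasonality)
    # constrained fit is only defined when the constraint windows overlap
    # the record span
    rc <- tryCatch(
      fit_ramp(series$age_mid, series$seasonality,
               constrain_start = clip_interval(config$ramp_start_interval,
                                               series$age_mid),
               constrain_end = clip_interval(config$ramp_end_interval,
                                             series$age_mid)),
      error = function(e) NULL)
    ok <- !is.na(series$seasonality)
    before <- series$seasonality[ok & series$age_mid >= ru$t_mid]
    after <- series$seasonality[ok & series$age_mid < ru$t_mid]
    mw <- if (length(before) >= 2L && length(after) >= 2L) {
      compare_groups(before, after, test = "mann_whitney")
    } else NULL
    list(thresholds = thresholds, series = series, ramp_u = ru,
         ramp_c = rc, test = mw)
  })

  say("variability")
  vari <- stage("variability", {
    prep <- prepare_series(annual, value = "u37_gc")
    filt <- bandpass_filter(prep$anomaly, 2, 8)
    blocks <- windowed_variability(filt, config$variability_window)
    blocks <- correct_variability(blocks, annual$n_spots, config$noise,
                                  config$calib,
                                  domain = config$variability_domain)
    blocks$age_mid <- vapply(seq_len(nrow(blocks)), function(b)
      mean(annual$age[blocks$start[b]:blocks$end[b]]), 0)
    older <- blocks$age_mid > config$variability_split
    tt <- if (sum(older) >= 2L && sum(!older) >= 2L) {
      compare_groups(blocks$corrected_sd_c[older],
                     blocks$corrected_sd_c[!older], test = "t")
    } else NULL
    spec <- redfit_spectrum(prep$anomaly)
    wav <- morlet_wavelet(prep$anomaly)
    list(prep = prep, filtered = filt, blocks = blocks, test = tt,
         spectrum = spec, wavelet = wav)
  })

  recovery <- list(
    true_seasonality_levels = range(truth$seasonality),
    fitted_levels = c(before = seas$ramp_u$level_before,
                      after = seas$ramp_u$level_after),
    true_mean_sst = config$scenario$mean_sst,
    reconstructed_window_means = window_means$mean,
    missing_years = sum(annual$missing))

  result <- list(truth = truth, table = table, age_model = age_model,
                 annual = annual, window_means = window_means,
                 thresholds = seas$thresholds, seasonal = seas$series,
                 ramp_unconstrained = seas$ramp_u,
                 ramp_constrained = seas$ramp_c,
                 seasonality_test = seas$test,
                 amplitude = amplitude_from_seasonality(
                   max(0, seas$ramp_u$level_after - seas$ramp_u$level_before)),
                 variability = vari$blocks,
                 variability_test = vari$test,
                 spectrum = vari$spectrum, wavelet = vari$wavelet,
                 recovery = recovery, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(config)
    write_with_header(
      data.frame(age_kyr_b2k = annual$age, n_spots = annual$n_spots,
                 u37_msi = annual$u37_msi, u37_gc = annual$u37_gc,
                 sst_c = annual$sst, missing = annual$missing),
      file.path(out_dir, "annual_series.csv"), hdr)
    write_with_header(
      data.frame(age_mid = seas$series$age_mid,
                 sst_nonupw = seas$series$sst_nonupw,
                 sst_upw = seas$series$sst_upw,
                 seasonality_c = seas$series$seasonality,
                 n_nonupw = seas$series$n_nonupw,
                 n_upw = seas$series$n_upw),
      file.path(out_dir, "seasonal_series.csv"), hdr)
    write_with_header(
      data.frame(age_mid = vari$blocks$age_mid,
                 raw_sd_c = vari$blocks$sd / config$calib$slope,
                 corrected_sd_c = vari$blocks$corrected_sd_c,
                 n_years = vari$blocks$n_years),
      file.path(out_dir, "variability_blocks.csv"), hdr)
    write_with_header(seas$thresholds,
                      file.path(out_dir, "season_thresholds.csv"), hdr)
    ramps <- list(provenance = hdr,
                  unconstrained = unclass(seas$ramp_u),
                  constrained = unclass(seas$ramp_c),
                  recovery = recovery)
    jsonlite::write_json(ramps, file.path(out_dir, "ramp_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Read a pipeline run configuration from a YAML file
#'
#' Scalar fields under `scenario:`, `calib:`, `noise:` and top-level
#' analysis settings override the corresponding defaults of
#' [scenario_config()], [calibration_config()], [noise_model()] and
#' [pipeline_config()].  The true seasonality step can be set via
#' `scenario: {seasonality_old: 0.8, seasonality_young: 1.8,
#' seasonality_step_age: 11.64}`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scn <- y$scenario
  if (!is.null(scn)) {
    step <- c(scn$seasonality_old, scn$seasonality_young,
              scn$seasonality_step_age)
    scn$seasonality_old <- scn$seasonality_young <-
      scn$seasonality_step_age <- NULL
    scenario <- do.call(scenario_config, scn)
    if (length(step) == 3L) {
      scenario$seasonality_fn <- local({
        s <- step
        function(age) ifelse(age > s[3L], s[1L], s[2L])
      })
    }
  } else {
    scenario <- scenario_config()
  }
  calib <- if (is.null(y$calib)) calibration_config() else
    do.call(calibration_config, y$calib)
  noise <- if (is.null(y$noise)) noise_model() else
    do.call(noise_model, y$noise)
  extra <- y[setdiff(names(y), c("scenario", "calib", "noise"))]
  do.call(pipeline_config,
          c(list(scenario = scenario, calib = calib, noise = noise), extra))
}

clip_interval <- function(interval, ages) {
  rng <- range(ages)
  lo <- max(interval[1L], rng[1L])
  hi <- min(interval[2L], rng[2L])
  if (lo > hi) interval else c(lo, hi)
}
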