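#' Proxy calibration configuration
#'
#' Holds the constants linking the MSI-scale U37K' index to gas
#' chromatography (GC) equivalents and to SST.  The GC-equivalence factor
#' is the measured mean ratio between GC-FID and MSI U37K' values of whole
#' slices (1.194, SD 0.021); the linear calibration is the classical
#' global core-top regression `U37K' = slope * SST + intercept` with
#' slope 0.033 per degC and intercept 0.044.
#'
#' @param gc_factor GC/MSI U37K' scaling factor.
#' @param slope calibration slope, U37K' units per degC.
#' @param intercept calibration intercept, U37K' units.
#' @param gc_factor_sd measured SD of the scaling factor (metadata only).
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(gc_factor = 1.194, slope = 0.033,
                               intercept = 0.044, gc_factor_sd = 0.021) {
  if (slope <= 0) stop("config error: slope must be positive", call. = FALSE)
  if (gc_factor <= 0) stop("config error: gc_factor must be positive",
                           call. = FALSE)
  structure(list(gc_factor = gc_factor, slope = slope, intercept = intercept,
                 gc_factor_sd = gc_factor_sd), class = "calibration_config")
}

#' Quality-control filter on laser spots
#'
#' Retains exactly the spots in which both alkenones were detected
#' (`i372 > 0` and `i373 > 0`) with signal-to-noise at or above the
#' threshold for both compounds.  Background-flagged spots are also
#' removed when the flag is present.
#'
#' @param table a [spot_table()].
#' @param sn_min signal-to-noise threshold (default 3).
#' @return the filtered `spot_table`; the number of removed spots is
#'   attached as attribute `n_removed` and reported via `message()`.
#' @export
qc_filter_spots <- function(table, sn_min = 3) {
  stopifnot(inherits(table, "spot_table"))
  s <- table$spots
  keep <- s$sn372 >= sn_min & s$sn373 >= sn_min & s$i372 > 0 & s$i373 > 0
  if ("background" %in% names(s)) keep <- keep & !s$background
  n_removed <- sum(!keep)
  table$spots <- s[keep, , drop = FALSE]
  rownames(table$spots) <- NULL
  attr(table, "n_removed") <- n_removed
  message(n_removed, " spot(s) removed by QC (S/N >= ", sn_min,
          ", both alkenones detected)")
  table
}

#' The U37K' alkenone unsaturation index
#'
#' `U37K' = C37:2 / (C37:2 + C37:3)`, computed on summed intensities.
#'
#' @param i372_sum,i373_sum summed intensities of the di- and
#'   tri-unsaturated C37 alkenone (non-negative, not both zero).
#' @return proxy values in `[0, 1]`.
#' @export
compute_uk37 <- function(i372_sum, i373_sum) {
  if (any(i372_sum < 0) || any(i373_sum < 0)) {
    stop("validation error: alkenone intensity sums must be non-negative",
         call. = FALSE)
  }
  tot <- i372_sum + i373_sum
  if (any(tot == 0)) {
    stop("undefined-value error: both alkenone sums are zero", call. = FALSE)
  }
  i372_sum / tot
}

#' Rescale an MSI-scale U37K' value to its GC equivalent
#'
#' Multiplies by the measured GC/MSI factor.  Values exceeding 1 after
#' scaling are physically out of range for the index; they are retained
#' (clamping would bias pooled statistics) but flagged with a warning and
#' in the returned `out_of_range` attribute.
#'
#' @param u_msi proxy value(s) on the MSI scale, in `[0, 1]`.
#' @param calib a [calibration_config()].
#' @return GC-equivalent proxy value(s) with attribute `out_of_range`.
#' @export
to_gc_equivalent <- function(u_msi, calib = calibration_config()) {
  if (any(u_msi < 0, na.rm = TRUE)) {
    stop("validation error: negative U37K' input", call. = FALSE)
  }
  out <- calib$gc_factor * u_msi
  flag <- !is.na(out) & out > 1
  if (any(flag)) {
    warning(sum(flag), " GC-equivalent value(s) > 1 (flagged, not clamped)",
            call. = FALSE)
  }
  attr(out, "out_of_range") <- flag
  out
}

#' Linear U37K'-SST calibration
#'
#' Forward: `SST = (u_gc - intercept) / slope`; inverse is its exact
#' inverse, `u_gc = slope * SST + intercept`.
#'
#' @param x GC-equivalent proxy value(s) (forward) or SST in degC
#'   (inverse).
#' @param calib a [calibration_config()].
#' @param direction `"forward"` (proxy to degC) or `"inverse"`.
#' @return SST in degC, or proxy values.
#' @export
calibrate_sst <- function(x, calib = calibration_config(),
                          direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (direction == "forward") (x - calib$intercept) / calib$slope
  else calib$slope * x + calib$intercept
}

#' Pool QC-passed spot intensities into annual horizons
#'
#' Sums the two alkenone intensities over all spots whose age falls in the
#' same 1-year bin.  Bins are half-open on the age (kyr b2k) axis with a
#' spot exactly on a boundary assigned to the younger year.  Bins with
#' fewer than `min_spots` qualifying spots are marked missing: their proxy
#' value would not satisfy the pooled-precision quality criterion.
#'
#' @param table a QC-filtered [spot_table()].
#' @param ages per-spot ages (kyr b2k), same order as `table$spots`.
#' @param age_breaks increasing vector of year-bin edges (kyr b2k).  If
#'   `NULL`, 1-yr bins spanning the age range, aligned to integer
#'   millennia-of-a-kyr (0.001) ticks.
#' @param min_spots minimum number of spots per annual horizon (default 10).
#' @return data frame of class `annual_series`, oldest year first: `age`
#'   (bin midpoint), `n_spots`, `i372_sum`, `i373_sum`, `missing`.
#' @export
pool_annual <- function(table, ages, age_breaks = NULL, min_spots = 10) {
  stopifnot(inherits(table, "spot_table"))
  if (length(ages) != nrow(table$spots)) {
    stop("validation error: one age per spot is required", call. = FALSE)
  }
  if (any(is.na(ages))) {
    stop("validation error: NaN/NA spot ages", call. = FALSE)
  }
  if (is.null(age_breaks)) {
    if (length(ages) == 0L) {
      stop("validation error: no spots to pool; supply explicit age_breaks ",
           "for an empty table", call. = FALSE)
    }
    dy <- 0.001
    lo <- floor(min(ages) / dy) * dy
    hi <- ceiling(max(ages) / dy) * dy
    age_breaks <- seq(lo, hi, by = dy)
  }
  if (any(diff(age_breaks) <= 0)) {
    stop("validation error: age_breaks must be strictly increasing",
         call. = FALSE)
  }
  nb <- length(age_breaks) - 1L
  # bin b spans (age_breaks[b], age_breaks[b+1]]: a spot exactly on a
  # boundary belongs to the younger (smaller-age) year
  bin <- nb + 1L - findInterval(-ages, rev(-age_breaks),
                                rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= nb
  s <- table$spots[ok, , drop = FALSE]
  bin <- bin[ok]
  i372_sum <- i373_sum <- numeric(nb)
  if (nrow(s) > 0L) {
    sums <- rowsum(cbind(s$i372, s$i373), group = bin)
    at <- as.integer(rownames(sums))
    i372_sum[at] <- sums[, 1L]
    i373_sum[at] <- sums[, 2L]
  }
  n_spots <- tabulate(bin, nbins = nb)
  out <- data.frame(age = (age_breaks[-1L] + age_breaks[-(nb + 1L)]) / 2,
                    n_spots = n_spots,
                    i372_sum = i372_sum, i373_sum = i373_sum,
                    missing = n_spots < min_spots)
  out <- out[order(out$age, decreasing = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Annual SST reconstruction from a spot table
#'
#' Convenience wrapper chaining QC filtering, age assignment, annual
#' pooling, the U37K' index, GC-equivalence scaling and the linear
#' calibration.
#'
#' @param table a [spot_table()] with `delta_gs`/`background` computed (or
#'   not; QC then skips the background test).
#' @param age_model an [age_depth_model()].
#' @param calib a [calibration_config()].
#' @param sn_min,min_spots QC thresholds.
#' @param age_breaks optional year-bin edges, see [pool_annual()].
#' @return an `annual_series` data frame with additional columns
#'   `u37_msi`, `u37_gc`, `sst` (all `NA` for missing years).
#' @export
reconstruct_annual_sst <- function(table, age_model,
                                   calib = calibration_config(),
                                   sn_min = 3, min_spots = 10,
                                   age_breaks = NULL) {
  qc <- suppressMessages(qc_filter_spots(table, sn_min = sn_min))
  ages <- depth_to_age(age_model, spot_composite_depth(qc))
  ann <- pool_annual(qc, ages, age_breaks = age_breaks,
                     min_spots = min_spots)
  ann$u37_msi <- NA_real_
  ok <- !ann$missing
  ann$u37_msi[ok] <- compute_uk37(ann$i372_sum[ok], ann$i373_sum[ok])
  ann$u37_gc <- as.numeric(suppressWarnings(
    to_gc_equivalent(ann$u37_msi, calib)))
  ann$sst <- calibrate_sst(ann$u37_gc, calib)
  ann
}

#' Gaussian smoothing of an annual series
#'
#' Symmetric Gaussian kernel over `window` points (sigma = window / 6), the
#' classical "15-point Gaussian" smoother of annually resolved records.
#' Missing values are skipped with the remaining kernel weights
#' renormalised to sum to 1.
#'
#' @param x numeric series (may contain `NA`).
#' @param window odd kernel width in points (default 15).
#' @return the smoothed series, same length as `x`.
#' @export
smooth_gaussian <- function(x, window = 15) {
  n <- length(x)
  if (window > n) {
    stop("validation error: smoothing window larger than series",
         call. = FALSE)
  }
  if (window %% 2 == 0) window <- window + 1L
  half <- (window - 1L) / 2L
  w <- stats::dnorm(seq(-half, half), sd = window / 6)
  w <- w / sum(w)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    xi <- x[lo:hi]
    wi <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
    ok <- !is.na(xi)
    if (any(ok)) out[i] <- sum(xi[ok] * wi[ok]) / sum(wi[ok])
  }
  out
}

#' Windowed summary statistics of an annual series
#'
#' Arithmetic mean, SD and count of the non-missing years in each half-open
#' age window `[age_lo, age_hi)`.
#'
#' @param series an `annual_series` (needs columns `age`, `sst`).
#' @param windows list of two-element numeric vectors `c(age_lo, age_hi)`
#'   in kyr b2k, `age_lo < age_hi`.
#' @return data frame with `age_lo`, `age_hi`, `mean`, `sd`, `n`; empty
#'   windows have `n = 0` and `NA` statistics.
#' @export
window_stats <- function(series, windows) {
  stopifnot(is.data.frame(series), all(c("age", "sst") %in% names(series)))
  if (is.numeric(windows) && length(windows) == 2L) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    sel <- series$age >= w[1L] & series$age < w[2L] & !is.na(series$sst)
    v <- series$sst[sel]
    data.frame(age_lo = w[1L], age_hi = w[2L],
               mean = if (length(v) > 0L) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else
                 if (length(v) == 1L) 0 else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}
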