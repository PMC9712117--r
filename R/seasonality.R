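#' Elemental intensities binned by normalised greyscale
#'
#' Mean Ca, Fe, Ti and Si intensity per Delta-GS bin over the
#' non-background spots, the fingerprint used to anchor the season split:
#' in Cariaco-type varves Fe, Ti and Ca peak in the dark (rainy,
#' non-upwelling) laminae and Si (biogenic opal from diatoms) peaks in the
#' light (upwelling) laminae.
#'
#' @param table a [spot_table()] with `delta_gs` computed
#'   (see [compute_delta_gs()]).
#' @param bin_size Delta-GS bin width (default 5 greyscale units).
#' @return data frame of class `elemental_profile`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `n`, `ca`, `fe`, `ti`, `si` (mean intensities; `NA` and
#'   `empty = TRUE` for spotless bins).
#' @export
elemental_gs_profile <- function(table, bin_size = 5) {
  stopifnot(inherits(table, "spot_table"))
  s <- table$spots
  if (!"delta_gs" %in% names(s) || all(is.na(s$delta_gs))) {
    stop("delta_gs must be computed first (see compute_delta_gs)",
         call. = FALSE)
  }
  s <- s[!is.na(s$delta_gs), , drop = FALSE]
  b <- floor(s$delta_gs / bin_size)
  rng <- range(b)
  bins <- seq(rng[1L], rng[2L])
  idx <- match(b, bins)
  n <- tabulate(idx, nbins = length(bins))
  m <- function(col) {
    out <- rep(NA_real_, length(bins))
    sums <- rowsum(s[[col]], group = idx)
    at <- as.integer(rownames(sums))
    out[at] <- sums[, 1L] / n[at]
    out
  }
  out <- data.frame(bin_lo = bins * bin_size,
                    bin_hi = (bins + 1) * bin_size,
                    bin_mid = (bins + 0.5) * bin_size,
                    n = n,
                    ca = m("ca"), fe = m("fe"), ti = m("ti"), si = m("si"))
  out$empty <- out$n == 0L
  attr(out, "bin_size") <- bin_size
  class(out) <- c("elemental_profile", "data.frame")
  out
}

pooled_sst <- function(i372, i373, calib) {
  if (length(i372) == 0L || (sum(i372) + sum(i373)) == 0) return(NA_real_)
  u <- compute_uk37(sum(i372), sum(i373))
  calibrate_sst(as.numeric(suppressWarnings(to_gc_equivalent(u, calib))),
                calib)
}

#' Find the greyscale threshold separating the two depositional seasons
#'
#' Searches integer Delta-GS cut values for the one that maximises the
#' difference between pooled U37K'-derived SST of the spots below (darker:
#' non-upwelling season) and above (lighter: upwelling season) the cut,
#' subject to three constraints: the threshold must be (1) lighter than
#' the Delta-GS bins where Ca, Ti and Fe peak, (2) darker than the bin
#' where Si peaks, and (3) leave at least `min_fraction` of the spots on
#' each side; when (1) and (2) make (3) unattainable the fraction limit is
#' relaxed to `fallback_fraction`.  Ties in the SST difference are broken
#' toward the smallest absolute threshold.
#'
#' @param table a QC-filtered [spot_table()] (alkenone-bearing spots) with
#'   `delta_gs` computed; the search bins these spots at 1-GS-unit
#'   resolution.
#' @param profile an [elemental_gs_profile()] of the same window (usually
#'   computed from all non-background spots, not only alkenone-bearing
#'   ones).
#' @param calib a [calibration_config()].
#' @param min_fraction minimal fraction of spots per season (default 0.25).
#' @param fallback_fraction relaxed limit (default 0.15).
#' @param min_bin_count minimal spot count for a profile bin to be eligible
#'   as an elemental peak (default 25; sparsely populated extreme-GS bins
#'   otherwise dominate the argmax by chance).
#' @return object of class `season_threshold`: list with `threshold`
#'   (Delta-GS), `sst_dark`, `sst_light`, `sst_diff`, `frac_dark`,
#'   `frac_light`, `fallback_used`, `candidates` (the evaluated grid) and
#'   `elemental_peaks` (argmax bin mid per element).
#' @export
find_season_threshold <- function(table, profile,
                                  calib = calibration_config(),
                                  min_fraction = 0.25,
                                  fallback_fraction = 0.15,
                                  min_bin_count = 25) {
  stopifnot(inherits(table, "spot_table"),
            inherits(profile, "elemental_profile"))
  s <- table$spots
  s <- s[!is.na(s$delta_gs), , drop = FALSE]
  if (nrow(s) == 0L) {
    stop("no-threshold error: no alkenone-bearing spots with delta_gs",
         call. = FALSE)
  }
  eligible <- profile$n >= min_bin_count
  if (!any(eligible)) eligible <- profile$n > 0L
  peak_mid <- function(col) {
    v <- profile[[col]]
    v[!eligible] <- NA_real_
    profile$bin_mid[which.max(v)]
  }
  peak_hi <- function(col) {
    v <- profile[[col]]
    v[!eligible] <- NA_real_
    profile$bin_hi[which.max(v)]
  }
  peak_lo <- function(col) {
    v <- profile[[col]]
    v[!eligible] <- NA_real_
    profile$bin_lo[which.max(v)]
  }
  peaks <- c(ca = peak_mid("ca"), fe = peak_mid("fe"), ti = peak_mid("ti"),
             si = peak_mid("si"))
  t_min <- max(peak_hi("ca"), peak_hi("fe"), peak_hi("ti"))
  t_max <- peak_lo("si")
  cand <- seq(ceiling(t_min), floor(t_max))
  cand <- cand[cand >= t_min & cand <= t_max]
  if (length(cand) == 0L) {
    stop("no-threshold error: elemental constraints leave no candidate ",
         "threshold (dark peaks at ", t_min, ", Si peak at ", t_max, ")",
         call. = FALSE)
  }
  n_tot <- nrow(s)
  eval_cut <- function(t) {
    dark <- s$delta_gs < t
    nd <- sum(dark); nl <- n_tot - nd
    sst_d <- pooled_sst(s$i372[dark], s$i373[dark], calib)
    sst_l <- pooled_sst(s$i372[!dark], s$i373[!dark], calib)
    c(threshold = t, n_dark = nd, n_light = nl,
      frac_min = min(nd, nl) / n_tot,
      sst_dark = sst_d, sst_light = sst_l, diff = sst_d - sst_l)
  }
  grid <- as.data.frame(do.call(rbind, lapply(cand, eval_cut)))
  pick <- function(g) {
    g <- g[!is.na(g$diff), , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    best <- g[g$diff == max(g$diff), , drop = FALSE]
    best[which.min(abs(best$threshold)), , drop = FALSE]
  }
  fallback_used <- FALSE
  sel <- pick(grid[grid$frac_min >= min_fraction, , drop = FALSE])
  if (is.null(sel)) {
    fallback_used <- TRUE
    sel <- pick(grid[grid$frac_min >= fallback_fraction, , drop = FALSE])
  }
  if (is.null(sel)) {
    stop("no-threshold error: no candidate leaves >= ",
         100 * fallback_fraction, "% of spots on each side", call. = FALSE)
  }
  structure(list(threshold = sel$threshold,
                 sst_dark = sel$sst_dark, sst_light = sel$sst_light,
                 sst_diff = sel$diff,
                 frac_dark = sel$n_dark / n_tot,
                 frac_light = sel$n_light / n_tot,
                 fallback_used = fallback_used,
                 candidates = grid, elemental_peaks = peaks),
            class = "season_threshold")
}

#' Per-slice season thresholds
#'
#' Applies [find_season_threshold()] slice by slice: the greyscale scale and
#' lamina contrast can drift between thin sections, so the split is
#' anchored per 5-cm slice.  Slices where no valid threshold exists are
#' flagged unusable (`NA` threshold).
#'
#' @param full_table the complete [spot_table()] (all non-background spots)
#'   with `delta_gs` computed; source of the elemental profiles.
#' @param qc_table the QC-filtered alkenone spot table.
#' @param calib a [calibration_config()].
#' @param ... passed to [find_season_threshold()].
#' @return data frame: `slice_id`, `threshold`, `fallback_used`,
#'   `sst_diff`.
#' @export
season_thresholds_by_slice <- function(full_table, qc_table,
                                       calib = calibration_config(), ...) {
  out <- lapply(full_table$slices$slice_id, function(sid) {
    sub_full <- full_table
    sub_full$spots <- full_table$spots[full_table$spots$slice_id == sid, ,
                                       drop = FALSE]
    sub_qc <- qc_table
    sub_qc$spots <- qc_table$spots[qc_table$spots$slice_id == sid, ,
                                   drop = FALSE]
    res <- tryCatch({
      prof <- elemental_gs_profile(sub_full)
      find_season_threshold(sub_qc, prof, calib, ...)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(slice_id = sid, threshold = NA_real_,
                 fallback_used = NA, sst_diff = NA_real_)
    } else {
      data.frame(slice_id = sid, threshold = res$threshold,
                 fallback_used = res$fallback_used,
                 sst_diff = res$sst_diff)
    }
  })
  do.call(rbind, out)
}

#' Seasonal SST records and the seasonality series
#'
#' Splits the QC-passed spots into non-upwelling (darker than the
#' threshold) and upwelling (lighter) seasons, pools intensities per
#' 5-year bin and season, applies the U37K' index, GC-equivalence and
#' calibration, and returns per-bin seasonal SSTs together with their
#' difference (the seasonality, degC).  Bins with fewer than `min_spots`
#' spots in a season are missing for that season; the seasonality is
#' defined only where both seasons are present.
#'
#' @param table a QC-filtered [spot_table()] with `delta_gs`.
#' @param thresholds result of [season_thresholds_by_slice()], or a single
#'   Delta-GS value applied to all slices.
#' @param ages per-spot ages (kyr b2k), same order as `table$spots`.
#' @param bin_years temporal bin width in years (default 5).
#' @param min_spots minimum spots per season and bin (default 10).
#' @param calib a [calibration_config()].
#' @return data frame of class `seasonal_series`, oldest bin first:
#'   `age_mid`, `sst_nonupw`, `sst_upw`, `n_nonupw`, `n_upw`,
#'   `seasonality`.
#' @export
seasonal_sst_series <- function(table, thresholds, ages, bin_years = 5,
                                min_spots = 10,
                                calib = calibration_config()) {
  stopifnot(inherits(table, "spot_table"))
  s <- table$spots
  if (length(ages) != nrow(s)) {
    stop("validation error: one age per spot is required", call. = FALSE)
  }
  if (is.numeric(thresholds) && is.null(dim(thresholds))) {
    thr <- rep(thresholds[1L], nrow(s))
  } else {
    thr <- thresholds$threshold[match(s$slice_id, thresholds$slice_id)]
  }
  usable <- !is.na(thr) & !is.na(s$delta_gs)
  s <- s[usable, , drop = FALSE]
  ages <- ages[usable]
  thr <- thr[usable]
  dark <- s$delta_gs < thr

  db <- bin_years * 0.001
  lo <- floor(min(ages) / db) * db
  hi <- ceiling(max(ages) / db) * db
  breaks <- seq(lo, hi, by = db)
  nb <- length(breaks) - 1L
  bin <- nb + 1L - findInterval(-ages, rev(-breaks), rightmost.closed = TRUE)

  pool_side <- function(sel) {
    n <- tabulate(bin[sel], nbins = nb)
    i2 <- i3 <- numeric(nb)
    if (any(sel)) {
      sums <- rowsum(cbind(s$i372[sel], s$i373[sel]), group = bin[sel])
      at <- as.integer(rownames(sums))
      i2[at] <- sums[, 1L]; i3[at] <- sums[, 2L]
    }
    sst <- rep(NA_real_, nb)
    ok <- n >= min_spots & (i2 + i3) > 0
    if (any(ok)) {
      u <- compute_uk37(i2[ok], i3[ok])
      sst[ok] <- calibrate_sst(
        as.numeric(suppressWarnings(to_gc_equivalent(u, calib))), calib)
    }
    list(n = n, sst = sst)
  }
  nonupw <- pool_side(dark)
  upw <- pool_side(!dark)
  out <- data.frame(age_mid = (breaks[-1L] + breaks[-(nb + 1L)]) / 2,
                    sst_nonupw = nonupw$sst, sst_upw = upw$sst,
                    n_nonupw = nonupw$n, n_upw = upw$n)
  out$seasonality <- out$sst_nonupw - out$sst_upw
  out <- out[order(out$age_mid, decreasing = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("seasonal_series", "data.frame")
  out
}

#' Ramp (change-point) regression
#'
#' Least-squares fit of a constant-linear-constant "ramp": on the age
#' (kyr b2k) axis the series sits at `level_before` for ages at or above
#' `t_start` (older), changes linearly, and sits at `level_after` for ages
#' at or below `t_end` (younger).  Breakpoint pairs are searched
#' exhaustively on the observed time grid with the two levels estimated
#' analytically per pair; ties in residual sum of squares are broken
#' toward the shortest ramp duration.
#'
#' @param age observation ages, kyr b2k.
#' @param value observed series (e.g. seasonality, degC); `NA` dropped.
#' @param constrain_start optional age interval `c(lo, hi)` (kyr b2k) the
#'   ramp start (older breakpoint) must fall in.
#' @param constrain_end optional interval for the ramp end (younger
#'   breakpoint).
#' @param exclude_negative drop negative-valued observations before
#'   fitting (default TRUE, the convention for seasonality series where
#'   negative values are unphysical).
#' @return object of class `ramp_fit`: list with `t_start`, `t_end`,
#'   `t_mid`, `level_before`, `level_after`, `rss`, `rms`, `n_used`,
#'   `constrained`.
#' @export
fit_ramp <- function(age, value, constrain_start = NULL,
                     constrain_end = NULL, exclude_negative = TRUE) {
  keep <- !is.na(value) & !is.na(age)
  if (exclude_negative) keep <- keep & value >= 0
  age <- age[keep]; value <- value[keep]
  if (length(age) < 6L) {
    stop("validation error: at least 6 usable points required",
         call. = FALSE)
  }
  grid <- sort(unique(age))
  starts <- grid
  ends <- grid
  constrained <- !is.null(constrain_start) || !is.null(constrain_end)
  if (!is.null(constrain_start)) {
    starts <- grid[grid >= constrain_start[1L] & grid <= constrain_start[2L]]
  }
  if (!is.null(constrain_end)) {
    ends <- grid[grid >= constrain_end[1L] & grid <= constrain_end[2L]]
  }
  if (length(starts) == 0L || length(ends) == 0L) {
    stop("validation error: constraint interval contains no grid points",
         call. = FALSE)
  }
  best <- NULL
  for (ts in starts) {
    for (te in ends) {
      if (te > ts) next
      w <- if (ts == te) as.numeric(age >= ts) else
        pmin(pmax((age - te) / (ts - te), 0), 1)
      X <- cbind(after = 1 - w, before = w)
      fit <- stats::lm.fit(X, value)
      rss <- sum(fit$residuals^2)
      dur <- ts - te
      if (is.null(best) || rss < best$rss - 1e-12 ||
          (abs(rss - best$rss) <= 1e-12 && dur < best$dur)) {
        best <- list(ts = ts, te = te, rss = rss, dur = dur,
                     lv = fit$coefficients)
      }
    }
  }
  structure(list(t_start = best$ts, t_end = best$te,
                 t_mid = (best$ts + best$te) / 2,
                 level_before = unname(best$lv["before"]),
                 level_after = unname(best$lv["after"]),
                 rss = best$rss,
                 rms = sqrt(best$rss / length(value)),
                 n_used = length(value),
                 constrained = constrained),
            class = "ramp_fit")
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat(sprintf(paste0("ramp fit: %.3f -> %.3f kyr b2k (midpoint %.3f), ",
                     "levels %.3f -> %.3f, rms %.3f (n = %d%s)\n"),
              x$t_start, x$t_end, x$t_mid, x$level_before, x$level_after,
              x$rms, x$n_used, if (x$constrained) ", constrained" else ""))
  invisible(x)
}

#' Annual sinusoid amplitude implied by a season-mean difference
#'
#' If the annual SST cycle is sinusoidal, the two half-cycle means differ
#' by `4a / pi` for half-amplitude `a`; a season-mean difference `d`
#' therefore implies a peak-to-peak annual amplitude of `2a = (pi / 2) d`.
#'
#' @param d season-mean SST difference, degC (non-negative).
#' @return peak-to-peak annual amplitude, degC.
#' @export
amplitude_from_seasonality <- function(d) {
  if (any(d < 0)) {
    stop("validation error: season-mean difference must be non-negative",
         call. = FALSE)
  }
  (pi / 2) * d
}
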