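#' Analytical-noise model for pooled MSI proxy values
#'
#' The pooled-estimator precision of MSI-based U37K' decreases with the
#' number of spots pooled following a fitted power law
#' `SD = coeff * n^exponent` on the MSI proxy scale
#' (coefficient 0.0741, exponent -0.558, R-squared 0.838 in the underlying
#' replicate spray experiment).
#'
#' @param coeff power-law coefficient (proxy SD at n = 1).
#' @param exponent power-law exponent (negative).
#' @param r_squared fit quality of the underlying experiment (metadata).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(coeff = 0.0741, exponent = -0.558,
                        r_squared = 0.838) {
  if (coeff <= 0) stop("config error: coeff must be positive", call. = FALSE)
  if (exponent >= 0) stop("config error: exponent must be negative",
                          call. = FALSE)
  structure(list(coeff = coeff, exponent = exponent, r_squared = r_squared),
            class = "noise_model")
}

#' Analytical variability of a pooled proxy value
#'
#' Evaluates the power-law precision model at a spot count: the predicted
#' standard deviation (MSI proxy scale) of a U37K' value pooled over
#' `n_spots` spots.  Strictly decreasing in `n_spots`.
#'
#' @param n_spots number of spots pooled (>= 1).
#' @param model a [noise_model()].
#' @return proxy-scale standard deviation(s).
#' @export
analytical_variability <- function(n_spots, model = noise_model()) {
  stopifnot(inherits(model, "noise_model"))
  if (any(n_spots < 1)) {
    stop("validation error: n_spots must be >= 1", call. = FALSE)
  }
  model$coeff * n_spots^model$exponent
}

#' Prepare an annual series for frequency analysis
#'
#' Fills interior missing years by linear interpolation between the nearest
#' non-missing neighbours, then removes a linear least-squares trend,
#' producing a regular, zero-mean anomaly series.  Leading or trailing
#' missing runs cannot be interpolated and are an error.
#'
#' @param series an `annual_series` with columns `age` and a value column.
#' @param value name of the value column (default `"sst"`).
#' @param max_missing_frac maximal tolerated fraction of missing years.
#' @return list with `age`, `anomaly` (regular, detrended), `n_interp`
#'   (count of interpolated years), and `trend` (the removed fitted line).
#' @export
prepare_series <- function(series, value = "sst", max_missing_frac = 0.2) {
  stopifnot(is.data.frame(series), value %in% names(series))
  x <- series[[value]]
  n <- length(x)
  miss <- is.na(x)
  if (is.na(x[1L]) || is.na(x[n])) {
    stop("validation error: leading/trailing missing years cannot be ",
         "interpolated (no extrapolation)", call. = FALSE)
  }
  if (mean(miss) > max_missing_frac) {
    stop(sprintf("validation error: %.0f%% of years missing exceeds the %.0f%% limit",
                 100 * mean(miss), 100 * max_missing_frac), call. = FALSE)
  }
  n_interp <- sum(miss)
  if (n_interp > 0L) {
    x <- stats::approx(seq_len(n)[!miss], x[!miss], xout = seq_len(n))$y
  }
  t_idx <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t_idx), x)
  trend <- as.numeric(cbind(1, t_idx) %*% fit$coefficients)
  list(age = series$age, anomaly = x - trend, n_interp = n_interp,
       trend = trend)
}

hanning_taper <- function(m) 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))

#' Red-noise spectrum of a regular annual anomaly series
#'
#' Welch-segmented (default 2 segments with 50% overlap), Hanning-tapered
#' periodogram with frequency oversampling by zero padding, evaluated up to
#' the Nyquist frequency (0.5 per yr for annual data, i.e. a shortest
#' period of 2 years).  A first-order autoregressive (red-noise) background
#' is estimated from the series' lag-1 autocorrelation, scaled to the same
#' total power, and a 95% false-alarm level is derived from the chi-square
#' distribution of the spectral estimate about that background.
#'
#' @param x regular, detrended anomaly series (annual spacing).
#' @param dt sampling interval in years (default 1).
#' @param oversample frequency oversampling factor (default 2).
#' @param segments number of Welch segments at 50% overlap (default 2).
#' @return object of class `spectrum_result`: list with `freq` (per yr),
#'   `period` (yr), `power`, `background`, `fal95`, `phi` (estimated lag-1
#'   coefficient), `dof`.
#' @export
redfit_spectrum <- function(x, dt = 1, oversample = 2, segments = 2) {
  n <- length(x)
  if (n < 64L) {
    stop("validation error: series too short for spectral analysis (< 64)",
         call. = FALSE)
  }
  x <- x - mean(x)
  seg_len <- floor(2 * n / (segments + 1))    # 50% overlap
  step <- floor(seg_len / 2)
  taper <- hanning_taper(seg_len)
  nfft <- 2^ceiling(log2(seg_len * oversample))
  nfreq <- nfft %/% 2L + 1L
  pow <- numeric(nfreq)
  for (s in seq_len(segments)) {
    i0 <- (s - 1L) * step
    seg <- x[(i0 + 1L):(i0 + seg_len)]
    seg <- (seg - mean(seg)) * taper
    ft <- stats::fft(c(seg, rep(0, nfft - seg_len)))[seq_len(nfreq)]
    # normalise so the integral over [0, Nyquist] equals the tapered variance
    pow <- pow + (Mod(ft)^2) * dt / (sum(taper^2))
  }
  pow <- pow / segments
  freq <- (seq_len(nfreq) - 1L) / (nfft * dt)

  r1 <- stats::cor(x[-n], x[-1L])
  phi <- max(0, r1)
  bg <- (1 - phi^2) / (1 - 2 * phi * cos(2 * pi * freq * dt) + phi^2)
  # scale the theoretical AR(1) shape to the estimated spectrum's mean power
  bg <- bg * mean(pow[-1L]) / mean(bg[-1L])
  dof <- 2 * segments
  fal95 <- bg * stats::qchisq(0.95, dof) / dof

  structure(list(freq = freq, period = ifelse(freq > 0, 1 / freq, Inf),
                 power = pow, background = bg, fal95 = fal95,
                 phi = phi, dof = dof),
            class = "spectrum_result")
}

#' Most significant spectral peak within a period band
#'
#' @param spec a [redfit_spectrum()] result.
#' @param period_lo,period_hi band limits in years.
#' @param require_significant keep only peaks above the 95% false-alarm
#'   level.
#' @return the period (yr) of the highest qualifying peak, or `NA` if none.
#' @export
spectrum_peak <- function(spec, period_lo, period_hi,
                          require_significant = TRUE) {
  stopifnot(inherits(spec, "spectrum_result"))
  sel <- spec$period >= period_lo & spec$period <= period_hi
  if (require_significant) sel <- sel & spec$power > spec$fal95
  if (!any(sel)) return(NA_real_)
  spec$period[sel][which.max(spec$power[sel])]
}

#' Continuous Morlet wavelet transform
#'
#' Torrence-Compo-style continuous wavelet transform with the Morlet
#' mother wavelet (omega0 = 6) on a dyadic-plus-suboctave scale set,
#' with cone of influence from the e-folding time of the wavelet
#' (`sqrt(2) * scale`) and pointwise 95% significance against a
#' lag-1-autoregressive red-noise background.
#'
#' @param x regular, detrended anomaly series.
#' @param dt sampling interval in years.
#' @param dj suboctave resolution (default 1/4).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return object of class `wavelet_result`: list with `time`, `scale`,
#'   `period` (yr), `power` (scales x time), `coi` (maximal unaffected
#'   period per time step, yr), `signif95` (per-scale 95% level),
#'   `significant` (logical matrix), `phi`, `global` (time-averaged
#'   power).
#' @export
morlet_wavelet <- function(x, dt = 1, dj = 0.25, omega0 = 6) {
  n <- length(x)
  if (n < 64L) {
    stop("validation error: series too short for wavelet analysis (< 64)",
         call. = FALSE)
  }
  sigma2 <- stats::var(x)
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  omega <- 2 * pi * c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) / (nfft * dt)

  s0 <- 2 * dt
  jmax <- floor(log2(n * dt / s0) / dj)
  scale <- s0 * 2^(dj * (0:jmax))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  period <- scale * fourier_factor

  W <- matrix(0 + 0i, nrow = length(scale), ncol = n)
  for (j in seq_along(scale)) {
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * scale[j] / dt) *
      exp(-((scale[j] * omega - omega0)^2) / 2) * (omega > 0)
    w_full <- stats::fft(xf * psi_hat, inverse = TRUE) / nfft
    W[j, ] <- w_full[seq_len(n)]
  }
  power <- Mod(W)^2

  # cone of influence: e-folding time sqrt(2)*scale, expressed as a period
  edge_dist <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi <- fourier_factor * edge_dist / sqrt(2)

  r1 <- if (sigma2 > 0) stats::cor(x[-n], x[-1L]) else 0
  phi <- max(0, r1)
  fft_freq <- dt / period                   # equivalent Fourier frequency * dt
  bg <- sigma2 * (1 - phi^2) /
    (1 - 2 * phi * cos(2 * pi * fft_freq) + phi^2)
  signif95 <- bg * stats::qchisq(0.95, 2) / 2
  significant <- sweep(power, 1L, signif95, ">")

  structure(list(time = (seq_len(n) - 1) * dt, scale = scale,
                 period = period, power = power, coi = coi,
                 signif95 = signif95, significant = significant,
                 phi = phi, global = rowMeans(power)),
            class = "wavelet_result")
}

#' Zero-phase band-pass for interannual periods
#'
#' Band-pass between `period_hi` and `period_lo` years, realised as a
#' zero-phase (forward-backward) 4th-order Butterworth filter.  For annual
#' data the 2-yr short-period edge coincides with the Nyquist period, so
#' the filter reduces to a high-pass there; corner frequencies are placed
#' inside the transition bands such that the squared (two-pass) response
#' has gain of at least 0.9 across the passband and at most 0.2 below
#' 1/20 cycles per year.
#'
#' @param x regular series (annual spacing assumed via `dt`).
#' @param period_lo shortest passed period, years (>= 2, the Nyquist limit
#'   of annually binned data).
#' @param period_hi longest passed period, years.
#' @param dt sampling interval, years.
#' @return filtered series, same length.
#' @export
bandpass_filter <- function(x, period_lo = 2, period_hi = 8, dt = 1) {
  if (period_lo < 2 * dt) {
    stop("validation error: period_lo below the Nyquist period (2 samples)",
         call. = FALSE)
  }
  if (period_hi <= period_lo) {
    stop("validation error: period_hi must exceed period_lo", call. = FALSE)
  }
  if (all(x == 0)) return(x)
  nyq <- 0.5 / dt
  f_lo <- 1 / period_hi
  f_hi <- 1 / period_lo
  # 0.64: with |H|^2 two-pass response of a 4th-order Butterworth,
  # a corner at 0.64*f gives gain 1/(1+0.64^8) = 0.973 at f
  corner_lo <- 0.64 * f_lo
  if (f_hi >= 0.999 * nyq) {
    flt <- signal::butter(4, corner_lo / nyq, type = "high")
  } else {
    corner_hi <- min(f_hi / 0.64, 0.999 * nyq)
    flt <- signal::butter(4, c(corner_lo, corner_hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(flt, x))
}

#' Windowed standard deviation of a filtered series
#'
#' Non-overlapping blocks of `window` years; the SD of the band-pass
#' filtered signal per block quantifies interannual variability.  A
#' partial trailing block is dropped.
#'
#' @param x filtered, regular series.
#' @param window block length in samples/years (default 25).
#' @return data frame: `block`, `start`, `end` (sample indices), `sd`,
#'   `n_years`.
#' @export
windowed_variability <- function(x, window = 25) {
  if (window < 2) {
    stop("validation error: window must span at least 2 samples",
         call. = FALSE)
  }
  n_blocks <- length(x) %/% window
  if (n_blocks < 1L) {
    stop("validation error: series shorter than one window", call. = FALSE)
  }
  start <- (seq_len(n_blocks) - 1L) * window + 1L
  data.frame(block = seq_len(n_blocks), start = start,
             end = start + window - 1L,
             sd = vapply(start, function(i)
               stats::sd(x[i:(i + window - 1L)]), 0),
             n_years = window)
}

#' Correct windowed variability for analytical noise
#'
#' The observed band-passed variability of a pooled MSI record contains an
#' analytical component that grows as spot counts per year shrink.  Per
#' block, the mean analytical variability is the power-law prediction
#' averaged over the member years' spot counts, rescaled to the
#' GC-equivalent proxy scale by `gc_factor`; it is removed from the
#' observed block SD (floored at zero) and the residual proxy SD is
#' converted to degC by dividing by the calibration slope.
#'
#' @param blocks a [windowed_variability()] result on the GC-equivalent
#'   proxy scale.
#' @param n_spots_by_year integer vector of per-year spot counts for the
#'   same series the blocks were computed from.
#' @param model a [noise_model()].
#' @param calib a [calibration_config()].
#' @param domain `"sd"` subtracts standard deviations (the default
#'   convention of the method); `"variance"` subtracts variances
#'   (`sqrt(max(obs^2 - noise^2, 0))`), which is unbiased when the noise
#'   estimate is accurate.
#' @return the `blocks` data frame with columns `analytical_sd` (proxy),
#'   `corrected_sd` (proxy) and `corrected_sd_c` (degC) added.
#' @export
correct_variability <- function(blocks, n_spots_by_year,
                                model = noise_model(),
                                calib = calibration_config(),
                                domain = c("sd", "variance")) {
  domain <- match.arg(domain)
  if (any(is.na(n_spots_by_year))) {
    stop("validation error: missing spot counts", call. = FALSE)
  }
  ana <- vapply(seq_len(nrow(blocks)), function(b) {
    yrs <- blocks$start[b]:blocks$end[b]
    if (max(yrs) > length(n_spots_by_year)) {
      stop("validation error: spot counts shorter than the block span",
           call. = FALSE)
    }
    mean(analytical_variability(pmax(n_spots_by_year[yrs], 1), model)) *
      calib$gc_factor
  }, 0)
  blocks$analytical_sd <- ana
  blocks$corrected_sd <- if (domain == "sd") {
    pmax(blocks$sd - ana, 0)
  } else {
    sqrt(pmax(blocks$sd^2 - ana^2, 0))
  }
  blocks$corrected_sd_c <- blocks$corrected_sd / calib$slope
  blocks
}

#' Two-group location comparison
#'
#' Two-sided Welch t-test or Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param values_a,values_b numeric groups (each n >= 2).
#' @param test `"t"` or `"mann_whitney"`.
#' @return list with `statistic`, `p_value`, `test`, and `degenerate`
#'   (TRUE when both groups are constant and identical, where the t-test
#'   is undefined).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("t", "mann_whitney")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("validation error: each group needs at least 2 values",
         call. = FALSE)
  }
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (test == "t") {
    if (degenerate) {
      return(list(statistic = NA_real_, p_value = NA_real_, test = test,
                  degenerate = TRUE))
    }
    ht <- stats::t.test(values_a, values_b)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test,
       degenerate = degenerate)
}
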