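# independent brute-force season-threshold search used as an oracle:
# enumerates every integer cut, recomputing constraints from scratch
brute_force_threshold <- function(spots, calib = calibration_config(),
                                  min_fraction = 0.25,
                                  fallback_fraction = 0.15) {
  bin5 <- floor(spots$delta_gs / 5)
  peak_of <- function(col) {
    means <- tapply(spots[[col]], bin5, mean)
    as.numeric(names(means))[which.max(means)]
  }
  lo <- (max(peak_of("ca"), peak_of("fe"), peak_of("ti")) + 1) * 5 # bin_hi
  hi <- peak_of("si") * 5                                          # bin_lo
  cands <- seq(ceiling(lo), floor(hi))
  if (ceiling(lo) > floor(hi)) return(NULL)
  sst_of <- function(sel) {
    if (!any(sel) || sum(spots$i372[sel] + spots$i373[sel]) == 0)
      return(NA_real_)
    u <- sum(spots$i372[sel]) / sum(spots$i372[sel] + spots$i373[sel])
    (u * calib$gc_factor - calib$intercept) / calib$slope
  }
  res <- lapply(cands, function(tt) {
    dark <- spots$delta_gs < tt
    list(t = tt, frac = min(mean(dark), mean(!dark)),
         diff = sst_of(dark) - sst_of(!dark))
  })
  pick <- function(minf) {
    ok <- Filter(function(r) !is.na(r$diff) && r$frac >= minf, res)
    if (length(ok) == 0L) return(NULL)
    d <- vapply(ok, `[[`, 0, "diff")
    best <- ok[d == max(d)]
    best[[which.min(abs(vapply(best, `[[`, 0, "t")))]]
  }
  out <- pick(min_fraction)
  fallback <- FALSE
  if (is.null(out)) { out <- pick(fallback_fraction); fallback <- TRUE }
  if (is.null(out)) return(NULL)
  list(threshold = out$t, fallback_used = fallback)
}

random_season_table <- function(seed, n = 150) {
  set.seed(seed)
  dark <- runif(n) < 0.5
  gs <- round(rnorm(n, ifelse(dark, 120, 180), 15))
  gs <- pmin(pmax(gs, 40), 250)
  u <- ifelse(dark, 0.72, 0.68) + rnorm(n, 0, 0.05)
  u <- pmin(pmax(u, 0), 1)
  tot <- rlnorm(n, log(100), 0.4)
  tab <- spot_table(make_spots(n, gs = gs,
                               i372 = tot * u, i373 = tot * (1 - u),
                               ca = rlnorm(n, log(ifelse(dark, 200, 100)), 0.3),
                               fe = rlnorm(n, log(ifelse(dark, 200, 100)), 0.3),
                               ti = rlnorm(n, log(ifelse(dark, 200, 100)), 0.3),
                               si = rlnorm(n, log(ifelse(dark, 100, 200)), 0.3)),
                   make_slices())
  compute_delta_gs(tab)
}

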