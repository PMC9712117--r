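#' Read a monthly SST table
#'
#' Plain CSV with a `year` column and twelve monthly columns (January to
#' December, any names, in calendar order).
#'
#' @param path CSV file path.
#' @return data frame with `year` and columns `m1` to `m12` (degC).
#' @export
read_monthly_sst <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"year" %in% names(d) || ncol(d) != 13L) {
    stop("monthly SST file must have a 'year' column plus 12 monthly columns",
         call. = FALSE)
  }
  vals <- d[, setdiff(names(d), "year"), drop = FALSE]
  names(vals) <- paste0("m", 1:12)
  cbind(d["year"], vals)
}

#' Seasonality of one year of monthly SST
#'
#' Exhaustively splits the twelve months into two complementary blocks of
#' consecutive calendar months -- circular, so a season may wrap December
#' to January -- each at least `min_block` months long, and returns the
#' largest difference between the two block means together with the warm
#' block's months.
#'
#' @param monthly numeric vector of 12 monthly SST values (degC).
#' @param min_block minimal block length in months (default 3).
#' @return list with `seasonality` (degC, non-negative), `warm_months`
#'   (integer month numbers of the warm block, in circular order) and
#'   `warm_label` (e.g. `"May-Nov"`).
#' @export
monthly_seasonality <- function(monthly, min_block = 3) {
  if (length(monthly) != 12L || any(is.na(monthly))) {
    stop("validation error: exactly 12 non-missing monthly values required",
         call. = FALSE)
  }
  best <- list(seasonality = -Inf)
  for (start in 1:12) {
    for (len in min_block:(12 - min_block)) {
      block <- ((start - 1 + seq_len(len) - 1) %% 12) + 1
      other <- setdiff(1:12, block)
      d <- mean(monthly[block]) - mean(monthly[other])
      if (abs(d) > best$seasonality) {
        warm <- if (d >= 0) block else other
        best <- list(seasonality = abs(d), warm_months = warm)
      }
    }
  }
  mn <- month.abb[best$warm_months]
  best$warm_label <- paste0(mn[1L], "-", mn[length(mn)])
  best
}

#' Multi-year mean seasonality of monthly SST
#'
#' Applies [monthly_seasonality()] to every year, averages the per-year
#' seasonality and tallies the warm-season definitions.
#'
#' @param series data frame as returned by [read_monthly_sst()].
#' @param min_block minimal block length in months.
#' @return list with `mean_seasonality` (degC), `per_year` (data frame:
#'   `year`, `seasonality`, `warm_label`) and `warm_tally` (named counts
#'   of warm-season definitions, decreasing).
#' @export
multi_year_seasonality <- function(series, min_block = 3) {
  stopifnot(nrow(series) >= 1L)
  rows <- lapply(seq_len(nrow(series)), function(i) {
    r <- monthly_seasonality(as.numeric(series[i, paste0("m", 1:12)]),
                             min_block = min_block)
    data.frame(year = series$year[i], seasonality = r$seasonality,
               warm_label = r$warm_label, stringsAsFactors = FALSE)
  })
  per_year <- do.call(rbind, rows)
  list(mean_seasonality = mean(per_year$seasonality),
       per_year = per_year,
       warm_tally = sort(table(per_year$warm_label), decreasing = TRUE))
}
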