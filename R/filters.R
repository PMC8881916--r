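## Eligibility filters for abundance time series.
##
## A site's series enters the population model only if it is long enough,
## not dominated by null captures, and free of long observation gaps:
## short or hole-ridden series cannot support estimation of the temporal
## dynamics, and strings of zeroes destabilize the log-abundance layer.

#' Filter annual abundance series on length, null captures and gaps
#'
#' A site is retained iff (i) it has at least `min_years` sampled years,
#' (ii) at least a fraction `min_nonnull` of its sampled years had
#' non-null captures (both size classes pooled), and (iii) no run of more
#' than `max_gap` consecutive unsampled years occurs between its first and
#' last sampled year.
#'
#' @param series data frame with columns `site_id`, `year`, `count`
#'   (total individuals captured; `NA` = year not sampled, `0` = sampled
#'   with null capture).
#' @param min_years minimum number of sampled years (default 15).
#' @param min_nonnull minimum fraction of non-null captures (default 0.5).
#' @param max_gap longest tolerated run of consecutive missing years
#'   (default 3).
#' @return list with `retained` (site ids) and `report` (one row per site:
#'   `n_years`, `frac_nonnull`, `max_gap_run`, `retained`, `reason`).
#' @export
filter_time_series <- function(series, min_years = 15, min_nonnull = 0.5,
                               max_gap = 3) {
  for (nm in c("site_id", "year", "count"))
    if (!nm %in% names(series)) stop_invalid(paste0("series lacks column ", nm))
  rep_rows <- lapply(split(series, series$site_id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    sampled <- !is.na(d$count)
    yrs <- d$year[sampled]
    n_years <- length(yrs)
    frac_nonnull <- if (n_years) mean(d$count[sampled] > 0) else 0
    gap_run <- 0L
    if (n_years >= 2L) {
      # runs of unsampled calendar years strictly inside the series
      full <- seq(min(yrs), max(yrs))
      present <- full %in% yrs
      r <- rle(present)
      inner <- r$lengths[!r$values]
      if (length(inner)) gap_run <- max(inner)
    }
    reasons <- c(
      if (n_years < min_years)
        sprintf("only %d sampled years (< %d)", n_years, min_years),
      if (frac_nonnull < min_nonnull)
        sprintf("non-null fraction %.2f (< %.2f)", frac_nonnull, min_nonnull),
      if (gap_run > max_gap)
        sprintf("missing run of %d years (> %d)", gap_run, max_gap))
    data.frame(site_id = d$site_id[1L], n_years = n_years,
               frac_nonnull = frac_nonnull, max_gap_run = gap_run,
               retained = length(reasons) == 0L,
               reason = if (length(reasons)) paste(reasons, collapse = "; ")
                        else "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(retained = report$site_id[report$retained], report = report)
}

#' Convert an abundance panel to a filterable count series
#'
#' Total capture per site-year on the count scale (`exp(X) - 1`, the
#' inverse of the `log(count + 1)` convention), with `NA` at masked years.
#'
#' @param panel an `abundance_panel`.
#' @return data frame `site_id`, `year`, `count`.
#' @export
panel_to_series <- function(panel) {
  stopifnot(inherits(panel, "abundance_panel"))
  n <- nrow(panel$X1); T <- ncol(panel$X1)
  count <- round(exp(panel$X0) - 1) + round(exp(panel$X1) - 1)
  count[!panel$mask] <- NA
  data.frame(site_id = rep(panel$sites, T),
             year = rep(panel$years, each = n),
             count = as.vector(count))
}
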