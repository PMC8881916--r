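## Temperature and spatial covariates.
##
## The population model uses an array U indexed (j, site, year) with
## j in {T_mean, T_mean^2, T_var, T_var^2}: the z-scored annual mean and
## intra-annual variability of water temperature and the squares of the
## z-scored values.  Spatial covariates (elevation, latitude, haversine
## distance to the species' geographic range center) feed the model
## selection stage.

#' Names of the four temperature covariate columns of U
#' @keywords internal
#' @noRd
u_names <- function() c("tmean", "tmean2", "tvar", "tvar2")

#' Summarize daily water temperatures between consecutive sampling occasions
#'
#' For each sampling occasion at a site, computes the arithmetic mean and
#' the standard deviation (intra-annual variability) of the daily water
#' temperatures in the window ending at that occasion and starting the day
#' after the previous occasion.  For a site's first occasion the window is
#' either the 365 days preceding the occasion (`first_year = "year_before"`,
#' default) or the calendar year of the occasion up to its date
#' (`first_year = "calendar_year"`).
#'
#' @param temps data frame with columns `site_id`, `date` (`Date` or
#'   coercible), `temp_c`.
#' @param events data frame of sampling occasions with columns `site_id`,
#'   `date`.
#' @param min_days minimum number of daily values required in a window;
#'   windows below it yield `NA` summaries (recorded, not dropped).
#' @param first_year window convention for a site's first occasion.
#' @return data frame with columns `site_id`, `year`, `date`, `t_mean`,
#'   `t_var`, `n_days`.
#' @export
summarize_temperature <- function(temps, events, min_days = 30,
                                  first_year = c("year_before",
                                                 "calendar_year")) {
  first_year <- match.arg(first_year)
  for (nm in c("site_id", "date", "temp_c"))
    if (!nm %in% names(temps)) stop_invalid(paste0("`temps` lacks column ", nm))
  for (nm in c("site_id", "date"))
    if (!nm %in% names(events)) stop_invalid(paste0("`events` lacks column ", nm))
  temps$date <- as.Date(temps$date)
  events$date <- as.Date(events$date)

  out <- lapply(split(events, events$site_id), function(ev) {
    ev <- ev[order(ev$date), , drop = FALSE]
    tw <- temps[temps$site_id == ev$site_id[1L], , drop = FALSE]
    res <- lapply(seq_len(nrow(ev)), function(k) {
      end <- ev$date[k]
      start <- if (k > 1L) ev$date[k - 1L] + 1L
        else if (first_year == "year_before") end - 364L
        else as.Date(paste0(format(end, "%Y"), "-01-01"))
      x <- tw$temp_c[tw$date >= start & tw$date <= end]
      n <- sum(is.finite(x))
      data.frame(site_id = ev$site_id[1L],
                 year = as.integer(format(end, "%Y")),
                 date = end,
                 t_mean = if (n >= min_days) mean(x, na.rm = TRUE) else NA_real_,
                 t_var = if (n >= min_days) sd(x, na.rm = TRUE) else NA_real_,
                 n_days = n)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the temperature covariate array U
#'
#' z-scores the annual mean and variability of water temperature pooled
#' over all site-years, then forms the squared covariates as elementwise
#' squares of the z-scored values.
#'
#' @param summaries data frame with columns `site_id`, `year`, `t_mean`,
#'   `t_var` (one row per site-year, as from [summarize_temperature()]).
#' @return an object of class `covariate_panel`: a list with `values`
#'   (array `4 x n_sites x n_years`, j-dimension named
#'   `tmean, tmean2, tvar, tvar2`), `standardization` (means/SDs used),
#'   `sites`, `years`.
#' @export
build_U <- function(summaries) {
  for (nm in c("site_id", "year", "t_mean", "t_var"))
    if (!nm %in% names(summaries))
      stop_invalid(paste0("`summaries` lacks column ", nm))
  sites <- sort(unique(summaries$site_id))
  years <- sort(unique(summaries$year))
  std <- list()
  for (v in c("t_mean", "t_var")) {
    x <- summaries[[v]]
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L)
      stop_invalid(paste0(v, " has fewer than 2 distinct values (zero variance)"))
    std[[v]] <- c(mean = mean(x), sd = sd(x))
  }
  vals <- array(NA_real_, dim = c(4L, length(sites), length(years)),
                dimnames = list(u_names(), as.character(sites),
                                as.character(years)))
  i <- match(summaries$site_id, sites)
  t <- match(summaries$year, years)
  zm <- (summaries$t_mean - std$t_mean["mean"]) / std$t_mean["sd"]
  zv <- (summaries$t_var - std$t_var["mean"]) / std$t_var["sd"]
  vals[cbind(1L, i, t)] <- zm
  vals[cbind(2L, i, t)] <- zm^2
  vals[cbind(3L, i, t)] <- zv
  vals[cbind(4L, i, t)] <- zv^2
  structure(list(values = vals, standardization = std,
                 sites = sites, years = years),
            class = "covariate_panel")
}

#' Great-circle distance by the haversine formula
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @param radius_km Earth radius; the conventional mean radius 6371 km.
#' @return distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)   # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop_invalid("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop_invalid("longitude outside [-180, 180]")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Distance from each site to a geographic range center
#'
#' The center is supplied as coordinates (e.g., the centroid of IUCN range
#' polygons computed elsewhere); it is an input, never computed here.
#'
#' @param sites data frame with columns `longitude`, `latitude`.
#' @param center numeric length-2 vector `c(lon, lat)`.
#' @return numeric vector of haversine distances in km.
#' @export
distance_to_center <- function(sites, center) {
  if (missing(center) || is.null(center) || length(center) != 2L ||
      any(!is.finite(center)))
    stop_invalid("`center` must be c(lon, lat)")
  haversine_km(sites$longitude, sites$latitude, center[1L], center[2L])
}
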