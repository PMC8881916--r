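## Synthetic ground-truth generator.
##
## Emulates the structure of national electrofishing monitoring data:
## sites scattered over a France-sized window with an elevation gradient,
## site-varying dynamic coefficients drawn from normal hyper-distributions,
## two-size-class log-abundance dynamics with normal process error,
## two-normal length mixtures per sampling event, water-temperature
## covariates correlated with elevation, and missing-year patterns that
## respect the eligibility filters of the estimation stage.

#' Specification of a simulated ground truth
#'
#' Bundles the hyper-parameters of the site hierarchy, the process error
#' SDs and an optional spatial gradient injected into selected parameter
#' families.  Defaults are magnitudes typical of fitted values for
#' medium-lived cyprinids: productivity above one, clear negative density
#' dependence among >0+ fish, positive apparent recruitment and survival,
#' weak and mostly linear temperature effects.
#'
#' @param hyper_means named numeric vector over the 13 parameter families
#'   (see [family_names()]).
#' @param hyper_sds named non-negative numeric vector over the same
#'   families (spatial variability of each coefficient).
#' @param process_sds length-2 non-negative vector `c(sd0, sd1)`: process
#'   error SD of the 0+ and >0+ log-abundance equations.
#' @param spatial_gradient optional named list: for a parameter family,
#'   `list(covariate = "elevation", linear = , quadratic = )` adds a trend
#'   in the z-scored site covariate to that family's mean.
#' @param seed integer seed stored with the specification.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(hyper_means = NULL, hyper_sds = NULL,
                             process_sds = c(sd0 = 0.4, sd1 = 0.25),
                             spatial_gradient = NULL, seed = 1L) {
  fam <- family_names()
  mu <- c(alpha0 = -2.0, beta0 = 1.5,
          g0_tmean = 0.2, g0_tmean2 = -0.05,
          g0_tvar = 0.3, g0_tvar2 = -0.05,
          alpha1 = 1.5, beta1 = -2.0, delta1 = 0.4,
          g1_tmean = 0.1, g1_tmean2 = -0.05,
          g1_tvar = 0.1, g1_tvar2 = -0.05)
  sig <- c(alpha0 = 0.5, beta0 = 0.3,
           g0_tmean = 0.1, g0_tmean2 = 0.1,
           g0_tvar = 0.1, g0_tvar2 = 0.1,
           alpha1 = 0.2, beta1 = 0.3, delta1 = 0.15,
           g1_tmean = 0.1, g1_tmean2 = 0.1,
           g1_tvar = 0.1, g1_tvar2 = 0.1)
  if (!is.null(hyper_means)) mu[names(hyper_means)] <- hyper_means
  if (!is.null(hyper_sds)) sig[names(hyper_sds)] <- hyper_sds
  if (!all(fam %in% names(mu)) || !all(fam %in% names(sig)))
    stop_invalid("hyper parameters must be named by family_names()")
  if (any(sig < 0)) stop_invalid("hyper_sds must be non-negative")
  if (any(process_sds < 0)) stop_invalid("process_sds must be non-negative")
  if (!is.null(spatial_gradient)) {
    bad <- setdiff(names(spatial_gradient), fam)
    if (length(bad))
      stop_invalid(paste("unknown parameter families in spatial_gradient:",
                         paste(bad, collapse = ", ")))
  }
  structure(list(hyper_means = mu[fam], hyper_sds = sig[fam],
                 process_sds = setNames(as.numeric(process_sds),
                                        c("sd0", "sd1")),
                 spatial_gradient = spatial_gradient,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Generate site metadata
#'
#' Sites are placed uniformly in a longitude/latitude bounding box
#' (default roughly metropolitan France); elevations are drawn from a
#' right-skewed distribution over `elev_range` (most monitored reaches are
#' lowland), with a west-to-east trend so elevation correlates with
#' longitude as it does across the French hydrographic network.
#'
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param elev_range numeric `c(min, max)` elevation in m.
#' @return data frame `site_id`, `longitude`, `latitude`, `elevation`.
#' @export
generate_sites <- function(n_sites, seed = 1L,
                           bbox = c(-4.5, 7.5, 42.5, 51),
                           elev_range = c(0, 1500)) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop_invalid("n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    lon <- runif(n_sites, bbox[1L], bbox[2L])
    lat <- runif(n_sites, bbox[3L], bbox[4L])
    # beta(1.3, 3.5) keeps most sites lowland; longitude trend adds relief
    # toward the eastern mountain ranges
    base <- stats::rbeta(n_sites, 1.3, 3.5)
    trend <- 0.25 * (lon - bbox[1L]) / (bbox[2L] - bbox[1L])
    e <- pmin(1, pmax(0, base + trend * stats::rbeta(n_sites, 2, 2)))
    data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
               longitude = lon, latitude = lat,
               elevation = elev_range[1L] + e * diff(elev_range))
  })
}

#' Draw site-specific dynamic coefficients from the hyper-distributions
#'
#' Each site coefficient is Normal(hyper mean + optional spatial trend in
#' the z-scored site covariate, hyper SD).  With a zero hyper SD and no
#' gradient all sites share the hyper mean exactly.
#'
#' @param truth a [simulation_truth()] object.
#' @param sites site table from [generate_sites()].
#' @return data frame: `site_id` plus one column per parameter family.
#' @export
generate_parameters <- function(truth, sites) {
  stopifnot(inherits(truth, "simulation_truth"))
  fam <- family_names()
  n <- nrow(sites)
  with_seed(truth$seed, {
    out <- data.frame(site_id = sites$site_id)
    for (f in fam) {
      m <- rep(truth$hyper_means[[f]], n)
      g <- truth$spatial_gradient[[f]]
      if (!is.null(g)) {
        if (!g$covariate %in% names(sites))
          stop_invalid(paste0("gradient covariate '", g$covariate,
                              "' not found in site table"))
        x <- sites[[g$covariate]]
        z <- (x - mean(x)) / sd(x)
        m <- m + (g$linear %||% 0) * z + (g$quadratic %||% 0) * z^2
      }
      out[[f]] <- rnorm(n, m, truth$hyper_sds[[f]])
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate two-size-class log-abundance dynamics
#'
#' Runs the two-equation state model forward: the >0+ class follows a
#' modified stochastic Gompertz recursion (intercept, carryover of last
#' year's >0+ log-abundance, density and size-class-transition terms
#' divided by the log sampling area, temperature effects, area-change
#' offset); the 0+ class responds contemporaneously to >0+ abundance and
#' temperature with a log-area offset.  Process noise is additive normal
#' on the log scale; with zero process SDs the output equals the
#' deterministic recursion.
#'
#' @param params site coefficient table from [generate_parameters()].
#' @param U a `covariate_panel` (or plain `4 x n x T` array) aligned with
#'   `params` rows and `T` years.
#' @param areas sampling areas in m^2: scalar, per-site vector, or
#'   `n x T` matrix; all values must exceed 1 so `log(area) > 0`.
#' @param T number of years (>= 2).
#' @param x0 initial >0+ log-abundance per site (scalar recycled); stored
#'   as year 1.
#' @param process_sds `c(sd0, sd1)` process error SDs.
#' @param seed integer seed.
#' @return object of class `abundance_panel`: list with `X0`, `X1`
#'   (`n x T` log-abundance matrices), `S` (areas), `mask` (`n x T`
#'   logical, `TRUE` = observed), `sites`, `years`.
#' @export
simulate_abundances <- function(params, U, areas, T, x0,
                                process_sds = c(0.4, 0.25), seed = 1L) {
  if (T < 2) stop_invalid("T must be >= 2")
  n <- nrow(params)
  Uv <- if (inherits(U, "covariate_panel")) U$values else U
  if (!is.array(Uv) || length(dim(Uv)) != 3L || dim(Uv)[1L] != 4L ||
      dim(Uv)[2L] != n || dim(Uv)[3L] < T)
    stop_invalid("U must be a 4 x n_sites x T covariate array")
  S <- if (is.matrix(areas)) areas else matrix(areas, n, T)
  if (any(S <= 1)) stop_invalid("all sampling areas must exceed 1 m^2")
  lS <- log(S)
  x0 <- rep_len(x0, n)
  fam <- family_names()
  th <- as.matrix(params[, fam])

  with_seed(seed, {
    X0 <- X1 <- matrix(NA_real_, n, T)
    X1[, 1L] <- x0
    g0 <- th[, c("g0_tmean", "g0_tmean2", "g0_tvar", "g0_tvar2")]
    g1 <- th[, c("g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2")]
    u_at <- function(t) t(Uv[, , t])                      # n x 4
    lam0 <- function(t) th[, "alpha0"] + th[, "beta0"] * X1[, t] / lS[, t] +
      rowSums(g0 * u_at(t)) + lS[, t]
    X0[, 1L] <- lam0(1L) + rnorm(n, 0, process_sds[1L])
    for (t in 2:T) {
      lam1 <- th[, "alpha1"] + X1[, t - 1L] +
        th[, "beta1"] * X1[, t - 1L] / lS[, t - 1L] +
        th[, "delta1"] * X0[, t - 1L] / lS[, t - 1L] +
        rowSums(g1 * u_at(t)) + (lS[, t] - lS[, t - 1L])
      X1[, t] <- lam1 + rnorm(n, 0, process_sds[2L])
      X0[, t] <- lam0(t) + rnorm(n, 0, process_sds[1L])
    }
    abundance_panel(X0, X1, S,
                    mask = matrix(TRUE, n, T),
                    sites = params$site_id, years = seq_len(T))
  })
}

#' Construct an abundance panel
#'
#' @param X0,X1 `n x T` log-abundance matrices for the 0+ and >0+ classes.
#' @param S `n x T` sampling areas (m^2).
#' @param mask `n x T` logical; `TRUE` where the site-year was sampled.
#' @param sites,years identifiers for rows and columns.
#' @return object of class `abundance_panel`.
#' @export
abundance_panel <- function(X0, X1, S, mask = NULL, sites = NULL,
                            years = NULL) {
  n <- nrow(X1); T <- ncol(X1)
  if (is.null(mask)) mask <- matrix(TRUE, n, T)
  structure(list(X0 = X0, X1 = X1, S = S, mask = mask,
                 sites = sites %||% sprintf("S%03d", seq_len(n)),
                 years = years %||% seq_len(T)),
            class = "abundance_panel")
}

#' Simulate individual body lengths for sampling events
#'
#' Draws `n0` lengths from the 0+ normal component and `n1` from the >0+
#' component of a two-normal length mixture, retaining true class labels.
#' Non-positive draws (vanishingly rare at realistic means/SDs) are
#' redrawn so all lengths are positive.
#'
#' @param counts data frame with columns `n0`, `n1` (and optionally
#'   `event_id`), one row per sampling event.
#' @param mixture_spec list `mean0`, `sd0`, `mean1`, `sd1` in mm; the 0+
#'   mean must lie below the >0+ mean.
#' @param seed integer seed.
#' @return data frame `event_id`, `length_mm`, `true_class`
#'   (factor `0+`, `>0+`).
#' @export
simulate_lengths <- function(counts,
                             mixture_spec = list(mean0 = 60, sd0 = 10,
                                                 mean1 = 180, sd1 = 30),
                             seed = 1L) {
  ms <- mixture_spec
  if (ms$mean0 <= 0 || ms$mean1 <= 0)
    stop_invalid("component means must be positive")
  if (ms$mean0 >= ms$mean1)
    stop_invalid("0+ mean must be smaller than >0+ mean")
  if (any(c(counts$n0, counts$n1) < 0, na.rm = TRUE))
    stop_invalid("counts must be non-negative")
  if (is.null(counts$event_id))
    counts$event_id <- sprintf("E%04d", seq_len(nrow(counts)))
  rpos <- function(n, m, s) {
    x <- rnorm(n, m, s)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), m, s)
    x
  }
  with_seed(seed, {
    per_event <- rbind(counts$n0, counts$n1)
    ids <- rep(rep(counts$event_id, each = 2L), as.vector(per_event))
    cls <- rep(rep(c("0+", ">0+"), nrow(counts)), as.vector(per_event))
    lens <- numeric(length(ids))
    lens[cls == "0+"] <- rpos(sum(counts$n0), ms$mean0, ms$sd0)
    lens[cls == ">0+"] <- rpos(sum(counts$n1), ms$mean1, ms$sd1)
    data.frame(event_id = ids, length_mm = lens,
               true_class = factor(cls, levels = c("0+", ">0+")))
  })
}

#' Mask site-years as missing under a maximum-gap constraint
#'
#' Marks a fraction of interior site-years unobserved such that no run of
#' consecutive missing years exceeds `max_consecutive` and each site's
#' first and last year stay observed (so the series anchors of the state
#' model survive).  If the constraints make the requested fraction
#' infeasible, as many cells as possible are masked and a warning reports
#' the achieved fraction.
#'
#' @param panel an `abundance_panel`.
#' @param missing_fraction target fraction of site-years masked, in [0, 1).
#' @param max_consecutive longest tolerated run of missing years (>= 0).
#' @param seed integer seed.
#' @return the panel with an updated `mask`.
#' @export
inject_missingness <- function(panel, missing_fraction,
                               max_consecutive = 3, seed = 1L) {
  stopifnot(inherits(panel, "abundance_panel"))
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop_invalid("missing_fraction must be in [0, 1)")
  if (max_consecutive < 0) stop_invalid("max_consecutive must be >= 0")
  if (missing_fraction == 0) return(panel)
  n <- nrow(panel$X1); T <- ncol(panel$X1)
  target <- round(missing_fraction * n * T)
  with_seed(seed, {
    mask <- panel$mask
    cand <- which(matrix(TRUE, n, T), arr.ind = TRUE)
    cand <- cand[cand[, 2L] > 1L & cand[, 2L] < T, , drop = FALSE]
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    placed <- 0L
    run_ok <- function(row) {
      r <- rle(!mask[row, ])
      !any(r$lengths[r$values] > max_consecutive)
    }
    for (k in seq_len(nrow(cand))) {
      if (placed >= target) break
      i <- cand[k, 1L]; t <- cand[k, 2L]
      if (!mask[i, t]) next
      mask[i, t] <- FALSE
      if (run_ok(i)) placed <- placed + 1L else mask[i, t] <- TRUE
    }
    if (placed < target)
      warning(sprintf(
        "missingness constraints allowed only %d of %d requested cells (%.1f%%)",
        placed, target, 100 * placed / (n * T)))
    panel$mask <- mask
    panel
  })
}

#' Simulate daily water temperatures for a set of sites
#'
#' A seasonal sinusoid around a site mean that decreases with elevation,
#' year-to-year shifts of the annual mean, and day-to-day noise.  Annual
#' amplitude grows slightly with elevation so intra-annual variability
#' correlates with elevation, as the covariate stage assumes.
#'
#' @param sites site table from [generate_sites()].
#' @param years integer vector of calendar years.
#' @param seed integer seed.
#' @return data frame `site_id`, `date`, `temp_c`.
#' @export
generate_daily_temperatures <- function(sites, years, seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(sites)), function(i) {
      base <- 14 - 0.005 * sites$elevation[i]
      amp <- 4 + 0.0015 * sites$elevation[i]
      res <- lapply(years, function(y) {
        dates <- seq(as.Date(paste0(y, "-01-01")),
                     as.Date(paste0(y, "-12-31")), by = "day")
        doy <- as.integer(format(dates, "%j"))
        m <- base + rnorm(1L, 0, 0.6)
        data.frame(site_id = sites$site_id[i], date = dates,
                   temp_c = m - amp * cos(2 * pi * (doy - 15) / 365) +
                     rnorm(length(doy), 0, 1.0))
      })
      do.call(rbind, res)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Generate a model-ready temperature covariate panel
#'
#' Shortcut for tests and simulations that do not need daily series: draws
#' per-site-year temperature means and variabilities with an elevation
#' trend and builds the z-scored covariate array via [build_U()].
#'
#' @param sites site table.
#' @param n_years number of years.
#' @param seed integer seed.
#' @return a `covariate_panel`.
#' @export
generate_covariates <- function(sites, n_years, seed = 1L) {
  with_seed(seed, {
    n <- nrow(sites)
    grid <- expand.grid(site_id = sites$site_id, year = seq_len(n_years),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    elev <- sites$elevation[match(grid$site_id, sites$site_id)]
    grid$t_mean <- 14 - 0.005 * elev + rnorm(nrow(grid), 0, 0.8)
    grid$t_var <- 3 + 0.0015 * elev + pmax(0, rnorm(nrow(grid), 0, 0.5))
    build_U(grid)
  })
}
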