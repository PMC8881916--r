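## Numerical elasticity analysis.
##
## Using posterior-median coefficients, log-abundance of each size class
## is projected deterministically over the study period; each parameter
## family is then perturbed by a proportional amount (default 10%, linear
## and quadratic temperature terms together) and the projection re-run.
## The elasticity at a site-year is the proportional change of projected
## log-abundance per unit proportional change of the parameter:
##   e = ((theta_per - theta_ori) / theta_ori) / perturb_fraction.
## Note the perturbation fraction is a tuning constant, distinct from the
## survival-rate coefficient delta1.

elasticity_family_map <- function() {
  list(alpha0 = "alpha0", beta0 = "beta0",
       tmean0 = c("g0_tmean", "g0_tmean2"),
       tvar0 = c("g0_tvar", "g0_tvar2"),
       alpha1 = "alpha1", beta1 = "beta1", delta1 = "delta1",
       tmean1 = c("g1_tmean", "g1_tmean2"),
       tvar1 = c("g1_tvar", "g1_tvar2"))
}

#' Parameter families available for elasticity analysis
#'
#' The default analysis set comprises the eight families whose
#' contribution is mapped spatially: apparent recruitment (`beta0`) and
#' the two temperature families of the 0+ equation, plus productivity
#' (`alpha1`), density dependence (`beta1`), apparent survival (`delta1`)
#' and the two temperature families of the >0+ equation.  `alpha0` (the
#' 0+ intercept) is also accepted.
#'
#' @param default if `TRUE` return the default 8-family analysis set,
#'   otherwise all 9 recognized labels.
#' @return character vector.
#' @export
elasticity_families <- function(default = TRUE) {
  all9 <- names(elasticity_family_map())
  if (default) setdiff(all9, "alpha0") else all9
}

family_class <- function(family) {
  if (family %in% c("alpha0", "beta0", "tmean0", "tvar0")) 0L else 1L
}

#' Project log-abundance paths from posterior-median coefficients
#'
#' Deterministic forward recursion of both dynamic equations from each
#' site's first in-series year.  The predictor attached to the focal
#' parameter takes its observed values; every other coefficient's
#' predictor is held at its site-level time average (missing observed
#' values are also filled with the site average).  The >0+ carryover term
#' uses the projected trajectory (`mode = "iterative"`, default) or the
#' observed series (`mode = "onestep"`).  Offset terms always use the
#' observed sampling areas.
#'
#' @param theta `n x 13` matrix of site coefficients (e.g.
#'   `posterior_median_params(draws)$theta`).
#' @param panel an `abundance_panel`.
#' @param U `covariate_panel` or `4 x n x T` array.
#' @param focal parameter family whose predictor stays observed (see
#'   [elasticity_families()]), or `NULL` for all-average predictors.
#' @param mode `"iterative"` or `"onestep"`.
#' @return list `theta0`, `theta1` (`n x T` projected log-abundances, `NA`
#'   outside a site's series) with attribute `skipped_sites`.
#' @export
project_abundance <- function(theta, panel, U, focal = NULL,
                              mode = c("iterative", "onestep")) {
  mode <- match.arg(mode)
  if (!is.null(focal) && !focal %in% elasticity_families(default = FALSE))
    stop_invalid(paste0("unknown parameter family '", focal, "'"))
  Uv <- if (inherits(U, "covariate_panel")) U$values else U
  theta <- as.matrix(theta[, family_names(), drop = FALSE])
  n <- nrow(panel$X1); T <- ncol(panel$X1)
  lS <- log(panel$S)
  mask <- panel$mask
  present <- matrix(FALSE, n, T)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    obs <- which(mask[i, ])
    if (length(obs) < 2L) { skipped <- c(skipped, i); next }
    present[i, obs[1L]:obs[length(obs)]] <- TRUE
  }

  site_fill <- function(M, obs = mask) {
    # observed values with site-mean fill at unobserved cells
    out <- M
    out[!obs] <- NA
    mn <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- mn[idx[, 1L]]
    out
  }
  site_avg <- function(M) {
    # site-level time mean of the observed quantity, held constant
    m <- M; m[!mask] <- NA
    matrix(rowMeans(m, na.rm = TRUE), n, T)
  }
  lag1 <- function(M) cbind(NA, M[, -T, drop = FALSE])
  lag_mask <- lag1(mask); lag_mask[, 1L] <- FALSE

  ratio0 <- panel$X0 / lS                         # X0_t / log S_t
  ratio1 <- panel$X1 / lS                         # X1_t / log S_t
  pick <- function(M, is_focal, lagged = FALSE) {
    if (!is_focal) return(site_avg(M))
    if (lagged) site_fill(lag1(M), obs = lag_mask) else site_fill(M)
  }

  P_b0 <- pick(ratio1, identical(focal, "beta0"))
  P_b1 <- pick(ratio1, identical(focal, "beta1"), lagged = TRUE)
  P_d1 <- pick(ratio0, identical(focal, "delta1"), lagged = TRUE)
  PU <- array(NA_real_, dim(Uv))
  for (j in 1:4) {
    cls <- if (j <= 2) "tmean" else "tvar"
    PU[j, , ] <- pick(matrix(Uv[j, , ], n, T),
                      identical(focal, paste0(cls, "0")) ||
                        identical(focal, paste0(cls, "1")))
  }

  g0 <- theta[, c("g0_tmean", "g0_tmean2", "g0_tvar", "g0_tvar2"),
              drop = FALSE]
  g1 <- theta[, c("g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2"),
              drop = FALSE]
  x1_fill <- site_fill(panel$X1)

  th0 <- th1 <- matrix(NA_real_, n, T)
  for (i in seq_len(n)) {
    ts <- which(present[i, ])
    if (!length(ts)) next
    t0 <- ts[1L]
    th1[i, t0] <- x1_fill[i, t0]
    for (t in ts) {
      u <- PU[, i, t]
      th0[i, t] <- theta[i, "alpha0"] + theta[i, "beta0"] * P_b0[i, t] +
        sum(g0[i, ] * u) + lS[i, t]
      if (t > t0) {
        carry <- if (mode == "iterative") th1[i, t - 1L]
                 else x1_fill[i, t - 1L]
        th1[i, t] <- theta[i, "alpha1"] + carry +
          theta[i, "beta1"] * P_b1[i, t] +
          theta[i, "delta1"] * P_d1[i, t] +
          sum(g1[i, ] * u) + lS[i, t] - lS[i, t - 1L]
      }
    }
  }
  structure(list(theta0 = th0, theta1 = th1),
            skipped_sites = skipped, class = "abundance_projection")
}

#' Re-project with one parameter family perturbed
#'
#' Multiplies the focal family's coefficients by `1 + perturb_fraction`
#' at every site (for a temperature family, the linear and quadratic
#' coefficients move together) and re-runs the projection with the focal
#' predictor observed.
#'
#' @inheritParams project_abundance
#' @param family focal parameter family.
#' @param perturb_fraction proportional change (default 0.10).
#' @return projection list as in [project_abundance()].
#' @export
perturb_and_project <- function(theta, panel, U, family,
                                perturb_fraction = 0.10,
                                mode = c("iterative", "onestep")) {
  map <- elasticity_family_map()
  if (!family %in% names(map))
    stop_invalid(paste0("unknown parameter family '", family, "'"))
  thp <- as.matrix(theta[, family_names(), drop = FALSE])
  thp[, map[[family]]] <- thp[, map[[family]]] * (1 + perturb_fraction)
  project_abundance(thp, panel, U, focal = family, mode = mode)
}

#' Numerical elasticity from original and perturbed projections
#'
#' `e = ((theta_per - theta_ori) / theta_ori) / perturb_fraction`,
#' computed pointwise.  Points where `|theta_ori|` falls below `eps` are
#' excluded (`NA`) and counted, avoiding division blow-ups.
#'
#' @param theta_ori,theta_per numeric arrays of equal shape.
#' @param perturb_fraction proportional change used for the perturbation;
#'   must be non-zero.
#' @param eps exclusion threshold on `|theta_ori|`.
#' @return array of elasticities with attribute `n_excluded`.
#' @export
compute_elasticity <- function(theta_ori, theta_per,
                               perturb_fraction = 0.10, eps = 1e-6) {
  if (perturb_fraction == 0) stop_invalid("perturb_fraction must be non-zero")
  e <- ((theta_per - theta_ori) / theta_ori) / perturb_fraction
  small <- is.finite(theta_ori) & abs(theta_ori) < eps
  e[small] <- NA_real_
  attr(e, "n_excluded") <- sum(small)
  e
}

#' Full elasticity analysis over parameter families
#'
#' For each family: project with posterior-median coefficients, perturb,
#' and compute site-year elasticities on the log-abundance of the size
#' class the parameter acts on.  For >0+ families the anchored first year
#' (where original and perturbed projections coincide by construction) is
#' excluded from the means.
#'
#' @param theta `n x 13` site coefficient matrix (posterior medians).
#' @param panel an `abundance_panel`.
#' @param U covariates.
#' @param families families to analyse (default the 8-family set).
#' @param perturb_fraction proportional change (default 0.10).
#' @param mode projection mode.
#' @return object of class `elasticity_result`: `e` (list of `n x T`
#'   matrices per family), `site_mean` (`family x site`), `species_mean`
#'   (per family mean over all site-years used), `perturb_fraction`,
#'   `excluded` (count per family), `sites`.
#' @export
elasticity_analysis <- function(theta, panel, U,
                                families = elasticity_families(),
                                perturb_fraction = 0.10,
                                mode = "iterative") {
  e_list <- list()
  excl <- integer(0)
  for (f in families) {
    ori <- project_abundance(theta, panel, U, focal = f, mode = mode)
    per <- perturb_and_project(theta, panel, U, f,
                               perturb_fraction = perturb_fraction,
                               mode = mode)
    if (family_class(f) == 0L) {
      e <- compute_elasticity(ori$theta0, per$theta0, perturb_fraction)
    } else {
      e <- compute_elasticity(ori$theta1, per$theta1, perturb_fraction)
      # anchored first in-series year: projections coincide by construction
      for (i in seq_len(nrow(e))) {
        t0 <- which(is.finite(ori$theta1[i, ]))[1L]
        if (!is.na(t0)) e[i, t0] <- NA_real_
      }
    }
    excl[f] <- attr(e, "n_excluded")
    e_list[[f]] <- e
  }
  site_mean <- t(vapply(e_list, function(e) rowMeans(e, na.rm = TRUE),
                        numeric(nrow(panel$X1))))
  species_mean <- vapply(e_list, function(e) mean(e, na.rm = TRUE),
                         numeric(1))
  structure(list(e = e_list, site_mean = site_mean,
                 species_mean = species_mean,
                 perturb_fraction = perturb_fraction,
                 excluded = excl, sites = panel$sites),
            class = "elasticity_result")
}

#' Compare elasticity distributions between species
#'
#' Pairwise tests per parameter family on site-level mean elasticities:
#' Wilcoxon signed-rank on sites shared by both species (>= `min_pairs`),
#' falling back to the rank-sum test when site sets barely overlap;
#' p-values are Bonferroni-adjusted over all comparisons performed.
#'
#' @param results named list (one element per species) of
#'   `elasticity_result` objects.
#' @param min_pairs minimum shared sites for the paired test (default 6).
#' @param correction p-adjustment method (default `"bonferroni"`).
#' @return data frame: `family`, `species_a`, `species_b`, `test`, `n`,
#'   `p`, `p_adj`, `note`.
#' @export
compare_species <- function(results, min_pairs = 6,
                            correction = "bonferroni") {
  if (length(results) < 2L) stop_invalid("need at least 2 species")
  sp <- names(results)
  fams <- Reduce(intersect, lapply(results, function(r) rownames(r$site_mean)))
  rows <- list()
  for (f in fams) {
    for (a in seq_along(sp)) for (b in seq_along(sp)) {
      if (a >= b) next
      ra <- results[[a]]; rb <- results[[b]]
      xa <- setNames(ra$site_mean[f, ], ra$sites)
      xb <- setNames(rb$site_mean[f, ], rb$sites)
      shared <- intersect(names(xa)[is.finite(xa)], names(xb)[is.finite(xb)])
      if (length(shared) >= min_pairs) {
        d <- xa[shared] - xb[shared]
        p <- if (all(d == 0)) 1
             else suppressWarnings(wilcox.test(xa[shared], xb[shared],
                                               paired = TRUE)$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, species_a = sp[a], species_b = sp[b],
          test = "signed-rank", n = length(shared), p = p, note = "")
      } else if (sum(is.finite(xa)) >= min_pairs &&
                 sum(is.finite(xb)) >= min_pairs) {
        p <- suppressWarnings(wilcox.test(xa[is.finite(xa)],
                                          xb[is.finite(xb)])$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, species_a = sp[a], species_b = sp[b],
          test = "rank-sum", n = sum(is.finite(xa)) + sum(is.finite(xb)),
          p = p, note = "site sets disjoint; unpaired fallback")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, species_a = sp[a], species_b = sp[b],
          test = "skipped", n = length(shared), p = NA_real_,
          note = sprintf("only %d shared sites (< %d)", length(shared),
                         min_pairs))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  done <- !is.na(out$p)
  out$p_adj[done] <- p.adjust(out$p[done], method = correction)
  out
}
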