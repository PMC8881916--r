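## Spatial hypotheses on site-level elasticities.
##
## Four candidate OLS models per parameter family: an intercept-only null,
## and quadratic regressions on elevation, latitude (range-shift
## hypothesis) and haversine distance to the geographic range center
## (abundant-center hypothesis).  Candidates are compared by AIC
## (Gaussian maximum-likelihood form, residual variance counted as a
## parameter, as stats::AIC does); the best covariate model is also
## checked against the null with a likelihood-ratio test.

spatial_covariates <- function() c("elevation", "distance", "latitude")

#' Fit the four candidate spatial models to site-level elasticities
#'
#' Covariates are z-scored before the quadratic term is formed, which
#' keeps the design well conditioned.
#'
#' @param elasticities data frame with columns `site_id`, `value`
#'   (site-level mean elasticity of one parameter family).
#' @param sites data frame with columns `site_id`, `elevation`,
#'   `latitude`, `distance` (km to the range center, e.g. from
#'   [distance_to_center()]).
#' @param min_sites minimum number of complete sites (default 5).
#' @return object of class `candidate_fit`: `aic` (named: null,
#'   elevation, distance, latitude), `best_model`, `adj_r2` (best model),
#'   `lrt_p` (best vs null, chi-square df = 2; `NA` if the null wins),
#'   `coefficients` (best model), `n`, `skipped` (unusable candidates and
#'   why), `tie` flag.
#' @export
fit_candidates <- function(elasticities, sites, min_sites = 5) {
  d <- merge(elasticities, sites, by = "site_id")
  need <- c("value", spatial_covariates())
  if (!all(need %in% names(d)))
    stop_invalid(paste("need columns", paste(need, collapse = ", ")))
  d <- d[complete.cases(d[, need]) & is.finite(d$value), , drop = FALSE]
  if (nrow(d) < min_sites)
    stop(errorCondition(
      sprintf("only %d usable sites (< %d)", nrow(d), min_sites),
      class = c("fishdyn_insufficient_data", "error")))

  null_fit <- lm(value ~ 1, data = d)
  aics <- c(null = AIC(null_fit))
  fits <- list(null = null_fit)
  skipped <- character(0)
  for (cv in spatial_covariates()) {
    x <- d[[cv]]
    if (sd(x) == 0) {
      skipped[cv] <- "covariate constant across sites"
      aics[cv] <- NA_real_
      next
    }
    z <- (x - mean(x)) / sd(x)
    fits[[cv]] <- lm(d$value ~ z + I(z^2))
    aics[cv] <- AIC(fits[[cv]])
  }
  ok <- names(aics)[is.finite(aics)]
  best <- ok[which.min(aics[ok])]
  # ties break toward the simpler model: the null has fewer parameters
  tie <- FALSE
  if (best != "null" && is.finite(aics["null"]) &&
      aics["null"] == aics[best]) {
    best <- "null"; tie <- TRUE
  }
  bf <- fits[[best]]
  adj_r2 <- summary(bf)$adj.r.squared
  lrt_p <- if (best == "null") NA_real_ else {
    stat <- 2 * (as.numeric(logLik(bf)) - as.numeric(logLik(null_fit)))
    pchisq(stat, df = 2, lower.tail = FALSE)
  }
  structure(list(aic = aics[c("null", spatial_covariates())],
                 best_model = best, adj_r2 = adj_r2, lrt_p = lrt_p,
                 coefficients = coef(bf), n = nrow(d),
                 skipped = skipped, tie = tie),
            class = "candidate_fit")
}

#' Summarize model selection across parameter families
#'
#' @param results named list of `candidate_fit` objects, one per
#'   parameter family.
#' @return object of class `model_selection`: `table` (AICs, best model,
#'   adjusted R-squared, LRT p per family), `tally` (wins per spatial
#'   hypothesis) and `verdict` (`"range-shift"` when elevation/latitude
#'   wins dominate, `"abundant-center"` when distance does, `"null"`, or
#'   `"mixed"` on a tie).
#' @export
select_best <- function(results) {
  if (!length(results)) stop_invalid("results must be non-empty")
  tab <- do.call(rbind, lapply(names(results), function(f) {
    r <- results[[f]]
    data.frame(family = f,
               aic_null = r$aic[["null"]],
               aic_elevation = r$aic[["elevation"]],
               aic_distance = r$aic[["distance"]],
               aic_latitude = r$aic[["latitude"]],
               best_model = r$best_model, adj_r2 = r$adj_r2,
               lrt_p = r$lrt_p, tie = r$tie)
  }))
  rownames(tab) <- NULL
  tally <- c(range_shift = sum(tab$best_model %in% c("elevation", "latitude")),
             abundant_center = sum(tab$best_model == "distance"),
             null = sum(tab$best_model == "null"))
  top <- max(tally)
  winners <- names(tally)[tally == top]
  verdict <- if (length(winners) > 1L) "mixed"
             else c(range_shift = "range-shift",
                    abundant_center = "abundant-center",
                    null = "null")[[winners]]
  structure(list(table = tab, tally = tally, verdict = verdict),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Spatial model selection across", nrow(x$table), "parameter families\n")
  print(x$table, digits = 4)
  cat("wins - range-shift:", x$tally[["range_shift"]],
      "| abundant-center:", x$tally[["abundant_center"]],
      "| null:", x$tally[["null"]], "\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
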