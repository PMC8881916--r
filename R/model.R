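## Hierarchical Bayesian two-size-class population dynamics model.
##
## Observation/process layer (site i, year t, log-abundances X):
##   X0[i,t] ~ Normal(lambda0[i,t], sd0)
##   X1[i,t] ~ Normal(lambda1[i,t], sd1)
##   lambda0 = alpha0_i + beta0_i * X1[i,t]/log(S[i,t])
##             + sum_j gamma0_ij U[j,i,t] + log(S[i,t])
##   lambda1 = alpha1_i + X1[i,t-1] + beta1_i * X1[i,t-1]/log(S[i,t-1])
##             + delta1_i * X0[i,t-1]/log(S[i,t-1])
##             + sum_j gamma1_ij U[j,i,t] + log(S[i,t]/S[i,t-1])
## Hierarchy: each site coefficient ~ Normal(family mean, family SD);
## priors: family means ~ Normal(0, 10), family SDs and process SDs
## ~ half-Cauchy(scale).  Missing X cells between a site's first and last
## observed year are latent nodes sampled by the Gibbs sampler.

#' Names of the 13 site-varying parameter families
#'
#' Order: 0+ equation (intercept `alpha0`, apparent recruitment `beta0`,
#' four temperature coefficients `g0_*`), then >0+ equation (productivity
#' `alpha1`, density dependence `beta1`, apparent survival `delta1`, four
#' temperature coefficients `g1_*`).  Temperature coefficients follow the
#' U covariate order: linear mean, squared mean, linear variability,
#' squared variability.
#'
#' @return character vector of length 13.
#' @export
family_names <- function() {
  c("alpha0", "beta0", "g0_tmean", "g0_tmean2", "g0_tvar", "g0_tvar2",
    "alpha1", "beta1", "delta1",
    "g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2")
}

#' Prior settings for the hierarchical model
#'
#' @param mu_sd SD of the Normal(0, mu_sd) prior on family means.
#' @param hc_scale scale of the half-Cauchy prior on all SDs (family SDs
#'   and the two process SDs); 2.5 is the weakly-informative convention.
#' @return list of class `popdyn_priors`.
#' @export
model_priors <- function(mu_sd = 10, hc_scale = 2.5) {
  if (mu_sd <= 0 || hc_scale <= 0) stop_invalid("prior scales must be positive")
  structure(list(mu_sd = mu_sd, hc_scale = hc_scale),
            class = "popdyn_priors")
}

#' Assemble a population dynamics model from data
#'
#' Validates alignment between the abundance panel and the covariate
#' array, derives which site-years carry likelihood terms (a year
#' contributes only when it lies between the site's first and last
#' observed year; the >0+ equation additionally needs the predecessor year
#' in-series), and stores prior settings.
#'
#' @param panel an `abundance_panel`.
#' @param U a `covariate_panel` or `4 x n_sites x T` array aligned with
#'   the panel.
#' @param priors a [model_priors()] object.
#' @return object of class `popdyn_model`.
#' @export
build_model <- function(panel, U, priors = model_priors()) {
  stopifnot(inherits(panel, "abundance_panel"))
  Uv <- if (inherits(U, "covariate_panel")) U$values else U
  n <- nrow(panel$X1); T <- ncol(panel$X1)
  if (!is.array(Uv) || length(dim(Uv)) != 3L || dim(Uv)[1L] != 4L)
    stop_invalid("U must be a 4 x n_sites x T array")
  if (dim(Uv)[2L] != n || dim(Uv)[3L] != T)
    stop_invalid(sprintf(
      "U (%d sites x %d years) is misaligned with the panel (%d x %d)",
      dim(Uv)[2L], dim(Uv)[3L], n, T))
  present <- matrix(FALSE, n, T)
  for (i in seq_len(n)) {
    obs <- which(panel$mask[i, ])
    if (length(obs)) present[i, obs[1L]:obs[length(obs)]] <- TRUE
  }
  if (any(panel$S[present] <= 1, na.rm = TRUE))
    stop_invalid("sampling areas must exceed 1 m^2 wherever modelled")
  idx <- which(present)
  if (any(!is.finite(matrix(Uv, nrow = 4L)[, idx])))
    stop_invalid("U contains non-finite values at modelled site-years")
  structure(list(panel = panel, U = Uv, priors = priors,
                 present = present, n_sites = n, n_years = T,
                 families = family_names()),
            class = "popdyn_model")
}

#' Expected log-abundances under the two dynamic equations
#'
#' Computes the lambda arrays for both size classes from site coefficients
#' and data.  `lambda1` is `NA` in year 1 (no predecessor).
#'
#' @param theta `n x 13` matrix of site coefficients with
#'   [family_names()] columns.
#' @param X0,X1 `n x T` log-abundance matrices.
#' @param logS `n x T` log sampling areas.
#' @param U `4 x n x T` covariate array.
#' @return list `lambda0`, `lambda1` (`n x T` matrices).
#' @export
compute_lambda <- function(theta, X0, X1, logS, U) {
  n <- nrow(X1); T <- ncol(X1)
  theta <- as.matrix(theta[, family_names(), drop = FALSE])
  g0 <- theta[, c("g0_tmean", "g0_tmean2", "g0_tvar", "g0_tvar2"),
              drop = FALSE]
  g1 <- theta[, c("g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2"),
              drop = FALSE]
  lam0 <- lam1 <- matrix(NA_real_, n, T)
  for (t in seq_len(T)) {
    u <- matrix(U[, , t], nrow = 4L)           # 4 x n
    lam0[, t] <- theta[, "alpha0"] +
      theta[, "beta0"] * X1[, t] / logS[, t] +
      rowSums(g0 * t(u)) + logS[, t]
    if (t >= 2L)
      lam1[, t] <- theta[, "alpha1"] + X1[, t - 1L] +
        theta[, "beta1"] * X1[, t - 1L] / logS[, t - 1L] +
        theta[, "delta1"] * X0[, t - 1L] / logS[, t - 1L] +
        rowSums(g1 * t(u)) + logS[, t] - logS[, t - 1L]
  }
  list(lambda0 = lam0, lambda1 = lam1)
}

#' Joint log density of the hierarchical model
#'
#' Likelihood of the observed (non-masked) log-abundances, the hierarchy
#' of site coefficients around the family means, and the priors.  Used as
#' an independent check of the sampler's target; latent cells are taken at
#' the values stored in the panel.
#'
#' @param model a `popdyn_model`.
#' @param theta `n x 13` site coefficient matrix.
#' @param hyper list with `mu` (13), `sigma` (13), `sd0`, `sd1`.
#' @return scalar log density.
#' @export
log_density <- function(model, theta, hyper) {
  p <- model$panel
  lam <- compute_lambda(theta, p$X0, p$X1, log(p$S), model$U)
  obs <- p$mask & model$present
  use0 <- obs
  use1 <- obs & cbind(FALSE, model$present[, -model$n_years, drop = FALSE])
  ll <- sum(dnorm(p$X0[use0], lam$lambda0[use0], hyper$sd0, log = TRUE)) +
    sum(dnorm(p$X1[use1 & !is.na(lam$lambda1)],
              lam$lambda1[use1 & !is.na(lam$lambda1)], hyper$sd1,
              log = TRUE))
  fam <- family_names()
  hier <- sum(vapply(seq_along(fam), function(f)
    sum(dnorm(theta[, fam[f]], hyper$mu[f], hyper$sigma[f], log = TRUE)),
    numeric(1)))
  A <- model$priors$hc_scale
  lhc <- function(s) log(2) - log(pi * A * (1 + (s / A)^2))
  pri <- sum(dnorm(hyper$mu, 0, model$priors$mu_sd, log = TRUE)) +
    sum(lhc(hyper$sigma)) + lhc(hyper$sd0) + lhc(hyper$sd1)
  ll + hier + pri
}

#' Fit the hierarchical model by Gibbs sampling
#'
#' Conjugate multivariate-normal updates for the per-site coefficient
#' blocks and the family means, slice sampling for the half-Cauchy family
#' and process SDs, and Gibbs imputation of latent (masked) log-abundances.
#' Defaults follow the reference chain geometry: 3 chains of 11,000 total
#' iterations, the first 1,000 discarded as burn-in, retaining every 10th
#' draw.  Initial values are drawn from the priors with a distinct seed
#' per chain (half-Cauchy draws capped at 10 for numerical sanity).
#'
#' @param model a `popdyn_model`.
#' @param chains number of chains.
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded.
#' @param thin retain every `thin`-th iteration after burn-in.
#' @param seed integer seed; chain c uses `seed + 1000 * c`.
#' @return object of class `popdyn_draws`: `draws` array
#'   `(chain, iteration, parameter)` with hyper-parameters
#'   (`mu[...]`, `sigma[...]`, `proc_sd0`, `proc_sd1`) and site
#'   coefficients (`alpha0[i]`, ...), plus `meta`.
#' @export
fit_popdyn <- function(model, chains = 3, iterations = 11000,
                       burn_in = 1000, thin = 10, seed = 1L) {
  stopifnot(inherits(model, "popdyn_model"))
  if (chains < 1) stop_invalid("chains must be >= 1")
  if (burn_in >= iterations) stop_invalid("burn_in must be below iterations")
  if (thin < 1) stop_invalid("thin must be >= 1")
  p <- model$panel
  n <- model$n_sites; T <- model$n_years
  fam <- family_names()

  X0 <- p$X0; X1 <- p$X1
  # initialize latent cells at the site mean of observed values
  for (i in seq_len(n)) {
    lat <- model$present[i, ] & !p$mask[i, ]
    if (any(lat)) {
      X0[i, lat] <- mean(p$X0[i, p$mask[i, ]], na.rm = TRUE)
      X1[i, lat] <- mean(p$X1[i, p$mask[i, ]], na.rm = TRUE)
    }
  }
  X0[!model$present] <- 0; X1[!model$present] <- 0
  logS <- log(p$S); logS[!model$present] <- 1  # inert filler
  Ucube <- aperm(model$U, c(2L, 3L, 1L))       # n x T x 4

  if (!all(is.finite(X0[model$present])) || !all(is.finite(X1[model$present])))
    stop(errorCondition("non-finite abundances at modelled site-years",
                        class = c("fishdyn_initialization_error", "error")))

  n_kept <- floor((iterations - burn_in) / thin)
  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    out[[ch]] <- with_seed(seed + 1000L * ch, {
      init <- list(
        mu = rnorm(13L, 0, model$priors$mu_sd),
        sigma = pmin(10, abs(rcauchy(13L, 0, model$priors$hc_scale))) + 0.01,
        sd0 = pmin(10, abs(rcauchy(1L, 0, model$priors$hc_scale))) + 0.01,
        sd1 = pmin(10, abs(rcauchy(1L, 0, model$priors$hc_scale))) + 0.01)
      gibbs_popdyn_cpp(X0, X1,
                       matrix(as.integer(p$mask), n, T),
                       matrix(as.integer(model$present), n, T),
                       logS, Ucube,
                       model$priors$mu_sd, model$priors$hc_scale,
                       as.integer(iterations), as.integer(burn_in),
                       as.integer(thin),
                       init$mu, init$sigma, init$sd0, init$sd1)
    })
  }
  cn <- c(paste0("mu[", fam, "]"), paste0("sigma[", fam, "]"),
          "proc_sd0", "proc_sd1",
          unlist(lapply(fam, function(f) paste0(f, "[", seq_len(n), "]"))))
  draws <- array(NA_real_, dim = c(chains, n_kept, length(cn)),
                 dimnames = list(NULL, NULL, cn))
  for (ch in seq_len(chains)) draws[ch, , ] <- out[[ch]]
  structure(list(draws = draws,
                 meta = list(chains = chains, iterations = iterations,
                             burn_in = burn_in, thin = thin, seed = seed,
                             n_sites = n, n_years = T, families = fam,
                             sites = p$sites)),
            class = "popdyn_draws")
}

#' Pool draws across chains into a matrix
#' @param draws a `popdyn_draws`.
#' @return matrix (chains * kept iterations) x parameters.
#' @export
pool_draws <- function(draws) {
  d <- draws$draws
  m <- matrix(aperm(d, c(2L, 1L, 3L)), nrow = dim(d)[1L] * dim(d)[2L],
              dimnames = list(NULL, dimnames(d)[[3L]]))
  m
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio per parameter; values below
#' 1.1 are taken as evidence of convergence.
#'
#' @param draws a `popdyn_draws` (or a `chains x iterations x parameters`
#'   array).
#' @param threshold flag parameters whose statistic exceeds it.
#' @return named vector of R-hat values with attribute `"flagged"`.
#' @export
gelman_rubin <- function(draws, threshold = 1.1) {
  a <- if (inherits(draws, "popdyn_draws")) draws$draws else draws
  m <- dim(a)[1L]; n <- dim(a)[2L]
  if (m < 2L) stop_invalid("Gelman-Rubin diagnostics need at least 2 chains")
  rhat <- apply(a, 3L, function(x) {
    # x: chains x iterations
    means <- rowMeans(x)
    W <- mean(apply(x, 1L, var))
    B <- n * var(means)
    if (W <= 0) return(1)
    # estimates below 1 are sampling noise; report the floored statistic
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  })
  attr(rhat, "flagged") <- names(rhat)[rhat > threshold]
  rhat
}

#' Highest posterior density interval
#'
#' Shortest interval containing a fraction `prob` of the empirical
#' distribution.
#'
#' @param samples numeric vector (>= 2 values).
#' @param prob interval mass in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop_invalid("prob must be in (0, 1)")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop_invalid("need at least 2 samples")
  m <- max(1L, min(n, ceiling(prob * n)))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Proportional overlap of two posterior sample sets
#'
#' Overlap coefficient `sum(min(p_a, p_b)) * binwidth` on a shared
#' histogram grid spanning the pooled sample range (512 equal-width bins).
#' An overlap below 5% is the conventional evidence that two posteriors
#' differ.
#'
#' @param samples_a,samples_b numeric vectors.
#' @param bins number of grid bins.
#' @return overlap proportion in \[0, 1\].
#' @export
posterior_overlap <- function(samples_a, samples_b, bins = 512) {
  a <- samples_a[is.finite(samples_a)]; b <- samples_b[is.finite(samples_b)]
  if (!length(a) || !length(b)) stop_invalid("both sample sets must be non-empty")
  rng <- range(c(a, b))
  if (rng[1L] == rng[2L]) return(1)
  brk <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  da <- tabulate(findInterval(a, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) / length(a)
  db <- tabulate(findInterval(b, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) / length(b)
  sum(pmin(da, db))
}

#' Extract per-draw site coefficient matrices
#' @keywords internal
#' @noRd
draw_theta <- function(pooled, d, n, fam = family_names()) {
  th <- vapply(fam, function(f)
    as.numeric(pooled[d, paste0(f, "[", seq_len(n), "]")]), numeric(n))
  colnames(th) <- fam
  th
}

#' Posterior predictive check with a chi-square discrepancy
#'
#' For each retained draw, computes the discrepancy
#' `D = sum((X - lambda)^2 / sigma^2)` of the observed data and of a
#' replicate simulated from the same draw; the Bayesian p-value is the
#' fraction of draws where the replicate discrepancy exceeds the observed
#' one.  Values near 0.5 indicate a good fit; values near 0 or 1 indicate
#' misfit.  Computed separately per size class over site-years whose
#' lambda is a function of observed data only.
#'
#' @param draws a `popdyn_draws` with monitored site coefficients.
#' @param model the fitted `popdyn_model`.
#' @param max_draws cap on the number of pooled draws used (evenly
#'   thinned); `Inf` uses all.
#' @return list `p0`, `p1`, `n_draws`.
#' @export
posterior_predictive_check <- function(draws, model, max_draws = 1000) {
  pooled <- pool_draws(draws)
  nd <- nrow(pooled)
  if (!nd) stop_invalid("no retained draws")
  use <- if (nd > max_draws)
    unique(round(seq(1L, nd, length.out = max_draws))) else seq_len(nd)
  p <- model$panel
  n <- model$n_sites
  logS <- log(p$S)
  obs <- p$mask & model$present
  use1 <- obs & cbind(FALSE, p$mask[, -model$n_years, drop = FALSE] &
                        model$present[, -model$n_years, drop = FALSE])
  d0 <- d1 <- matrix(NA_real_, length(use), 2L)
  for (k in seq_along(use)) {
    dd <- use[k]
    th <- draw_theta(pooled, dd, n)
    sd0 <- pooled[dd, "proc_sd0"]; sd1 <- pooled[dd, "proc_sd1"]
    lam <- compute_lambda(th, p$X0, p$X1, logS, model$U)
    r0 <- (p$X0[obs] - lam$lambda0[obs]) / sd0
    rep0 <- rnorm(length(r0))
    d0[k, ] <- c(sum(r0^2), sum(rep0^2))
    l1 <- lam$lambda1[use1]
    r1 <- (p$X1[use1] - l1) / sd1
    rep1 <- rnorm(length(r1))
    d1[k, ] <- c(sum(r1^2), sum(rep1^2))
  }
  list(p0 = mean(d0[, 2L] > d0[, 1L]), p1 = mean(d1[, 2L] > d1[, 1L]),
       n_draws = length(use))
}

#' Posterior summary table
#'
#' @param object a `popdyn_draws`.
#' @param prob HPD interval mass.
#' @param ... unused.
#' @return data frame: `parameter`, `median`, `hpd_lower`, `hpd_upper`,
#'   `rhat` (NA with a single chain).
#' @export
summary.popdyn_draws <- function(object, prob = 0.95, ...) {
  pooled <- pool_draws(object)
  rhat <- if (dim(object$draws)[1L] >= 2L) gelman_rubin(object)
          else rep(NA_real_, ncol(pooled))
  hpd <- apply(pooled, 2L, hpd_interval, prob = prob)
  data.frame(parameter = colnames(pooled),
             median = apply(pooled, 2L, median),
             hpd_lower = hpd[1L, ], hpd_upper = hpd[2L, ],
             rhat = as.numeric(rhat), row.names = NULL)
}

#' Posterior medians of the site coefficients
#'
#' @param draws a `popdyn_draws`.
#' @return list with `theta` (`n x 13` matrix of per-site posterior
#'   medians) and `hyper` (medians of the family means/SDs and process
#'   SDs).
#' @export
posterior_median_params <- function(draws) {
  pooled <- pool_draws(draws)
  n <- draws$meta$n_sites
  fam <- family_names()
  med <- apply(pooled, 2L, median)
  theta <- vapply(fam, function(f)
    med[paste0(f, "[", seq_len(n), "]")], numeric(n))
  colnames(theta) <- fam
  rownames(theta) <- NULL
  list(theta = theta,
       hyper = list(mu = med[paste0("mu[", fam, "]")],
                    sigma = med[paste0("sigma[", fam, "]")],
                    sd0 = med[["proc_sd0"]], sd1 = med[["proc_sd1"]]))
}
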