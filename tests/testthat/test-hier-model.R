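# a small simulated study shared by several blocks in this file
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sites <- generate_sites(12, seed = 21)
      truth <- simulation_truth(seed = 22)
      params <- generate_parameters(truth, sites)
      U <- generate_covariates(sites, 16, seed = 23)
      panel <- simulate_abundances(params, U, areas = 500, T = 16,
                                   x0 = rep(4.5, 12),
                                   process_sds = truth$process_sds,
                                   seed = 24)
      panel <- inject_missingness(panel, 0.08, 3, seed = 25)
      cache <<- list(sites = sites, truth = truth, params = params,
                     U = U, panel = panel,
                     model = build_model(panel, U))
    }
    cache
  }
})

test_that("build_model validates alignment and areas", {
  st <- small_study()
  expect_s3_class(st$model, "popdyn_model")
  expect_error(build_model(st$panel, st$U$values[, 1:5, ]),
               class = "fishdyn_invalid_argument")
  bad <- st$panel; bad$S[2, 3] <- 0.5
  expect_error(build_model(bad, st$U), class = "fishdyn_invalid_argument")
})

test_that("lambda equations match a term-by-term oracle", {
  set.seed(31)
  n <- 2; T <- 5
  theta <- make_theta(n)
  for (f in family_names()) theta[, f] <- rnorm(n, 0, 0.5)
  X0 <- matrix(rnorm(n * T, 5, 1), n)
  X1 <- matrix(rnorm(n * T, 5, 1), n)
  logS <- matrix(runif(n * T, 4, 7), n)
  U <- array(rnorm(4 * n * T), c(4, n, T))
  got <- compute_lambda(theta, X0, X1, logS, U)
  want <- naive_lambda(theta, X0, X1, logS, U)
  expect_equal(got$lambda0, want$lambda0, tolerance = 1e-10)
  expect_equal(got$lambda1, want$lambda1, tolerance = 1e-10)

  # algebraic reduction: U = 0 and constant S
  theta0 <- make_theta(n, alpha1 = 1.2, beta1 = -0.4, delta1 = 0.3)
  lS <- matrix(5, n, T)
  red <- compute_lambda(theta0, X0, X1, lS, array(0, c(4, n, T)))
  expect_equal(red$lambda1[, 2],
               1.2 + X1[, 1] * (1 - 0.4 / 5) + 0.3 * X0[, 1] / 5,
               tolerance = 1e-12)
})

test_that("joint log density matches an independent recomputation", {
  st <- small_study()
  m <- st$model
  theta <- as.matrix(st$params[, family_names()])
  hyper <- list(mu = unname(st$truth$hyper_means),
                sigma = unname(st$truth$hyper_sds) + 0.05,
                sd0 = 0.4, sd1 = 0.25)
  got <- log_density(m, theta, hyper)

  # independent recomputation with naive loops
  p <- m$panel
  lam <- naive_lambda(theta, p$X0, p$X1, log(p$S), m$U)
  ll <- 0
  for (i in 1:nrow(p$X1)) for (t in 1:ncol(p$X1)) {
    if (!p$mask[i, t] || !m$present[i, t]) next
    ll <- ll + dnorm(p$X0[i, t], lam$lambda0[i, t], hyper$sd0, log = TRUE)
    if (t >= 2 && m$present[i, t - 1])
      ll <- ll + dnorm(p$X1[i, t], lam$lambda1[i, t], hyper$sd1, log = TRUE)
  }
  for (f in seq_along(family_names()))
    ll <- ll + sum(dnorm(theta[, f], hyper$mu[f], hyper$sigma[f],
                         log = TRUE))
  A <- m$priors$hc_scale
  lhc <- function(s) log(2 / (pi * A * (1 + (s / A)^2)))
  ll <- ll + sum(dnorm(hyper$mu, 0, 10, log = TRUE)) +
    sum(lhc(hyper$sigma)) + lhc(hyper$sd0) + lhc(hyper$sd1)
  expect_equal(got, ll, tolerance = 1e-8)
})

test_that("log density peaks at the noiseless trajectory", {
  sites <- generate_sites(1, seed = 41)
  truth <- simulation_truth(seed = 42)
  params <- generate_parameters(truth, sites)
  U <- generate_covariates(sites, 8, seed = 43)
  panel <- simulate_abundances(params, U, 500, 8, 4.5,
                               process_sds = c(0, 0), seed = 44)
  theta <- as.matrix(params[, family_names()])
  hyper <- list(mu = unname(truth$hyper_means),
                sigma = unname(truth$hyper_sds) + 0.05,
                sd0 = 0.05, sd1 = 0.05)
  base <- log_density(build_model(panel, U), theta, hyper)
  set.seed(45)
  for (k in 1:5) {
    pert <- panel
    pert$X0 <- pert$X0 + rnorm(length(pert$X0), 0, 0.05)
    pert$X1 <- pert$X1 + rnorm(length(pert$X1), 0, 0.05)
    expect_lt(log_density(build_model(pert, U), theta, hyper), base)
  }
})

test_that("the sampler is seed-deterministic and recovers a small study", {
  st <- small_study()
  d1 <- fit_popdyn(st$model, chains = 2, iterations = 700, burn_in = 200,
                   thin = 5, seed = 5)
  d2 <- fit_popdyn(st$model, chains = 2, iterations = 700, burn_in = 200,
                   thin = 5, seed = 5)
  expect_identical(d1$draws, d2$draws)
  expect_equal(dim(d1$draws), c(2L, 100L, 28L + 13L * 12L))

  d <- fit_popdyn(st$model, chains = 3, iterations = 2500, burn_in = 500,
                  thin = 5, seed = 6)
  s <- summary(d)
  hs <- s[grepl("^mu\\[", s$parameter), ]
  truth <- st$truth$hyper_means[gsub("mu\\[|\\]", "", hs$parameter)]
  cover <- truth >= hs$hpd_lower & truth <= hs$hpd_upper
  # desk-scale recovery: most family means covered, none grossly off
  expect_gte(mean(cover), 10 / 13)
  expect_lt(max(s$rhat[grepl("^mu|^proc", s$parameter)]), 1.2)

  expect_error(fit_popdyn(st$model, chains = 0),
               class = "fishdyn_invalid_argument")
  expect_error(fit_popdyn(st$model, iterations = 100, burn_in = 100),
               class = "fishdyn_invalid_argument")
})

test_that("Gelman-Rubin flags separated chains and accepts iid ones", {
  set.seed(51)
  iid <- array(rnorm(2 * 10000), c(2, 10000, 1),
               dimnames = list(NULL, NULL, "x"))
  r <- gelman_rubin(iid)
  expect_gte(r[["x"]], 1)
  expect_lt(r[["x"]], 1.01)

  apart <- array(c(rnorm(1000), rnorm(1000, 100)), c(2, 1000, 1),
                 dimnames = list(NULL, NULL, "x"))
  # chains filled chain-major: chain 1 ~ N(0,1), chain 2 ~ N(100,1)
  apart[1, , 1] <- rnorm(1000)
  apart[2, , 1] <- rnorm(1000, 100)
  expect_gt(gelman_rubin(apart)[["x"]], 10)

  one <- array(rnorm(100), c(1, 100, 1), dimnames = list(NULL, NULL, "x"))
  expect_error(gelman_rubin(one), class = "fishdyn_invalid_argument")
})

test_that("HPD intervals are the shortest prob-mass windows", {
  expect_equal(unname(hpd_interval(rep(3, 10))), c(3, 3))

  set.seed(52)
  z <- rnorm(1e6)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.02)
  expect_lt(abs(h[["upper"]] - 1.96), 0.02)

  u <- runif(2e5)
  hu <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(hu) - 0.95), 0.01)

  expect_error(hpd_interval(z, 1.2), class = "fishdyn_invalid_argument")
  expect_error(hpd_interval(numeric(1)), class = "fishdyn_invalid_argument")
})

test_that("posterior overlap matches the closed form for unit normals", {
  set.seed(53)
  a <- rnorm(3e5)
  expect_equal(posterior_overlap(a, a), 1, tolerance = 1e-12)
  expect_lt(posterior_overlap(a, rnorm(3e5, 100)), 1e-3)
  ov <- posterior_overlap(a, rnorm(3e5, 1))
  expect_lt(abs(ov - 2 * pnorm(-0.5)), 0.02)
  expect_error(posterior_overlap(numeric(0), a),
               class = "fishdyn_invalid_argument")
})

test_that("posterior predictive checks calibrate and detect misfit", {
  st <- small_study()
  d <- fit_popdyn(st$model, chains = 2, iterations = 1500, burn_in = 500,
                  thin = 5, seed = 7)
  ppc <- posterior_predictive_check(d, st$model)
  expect_gt(ppc$p0, 0.2); expect_lt(ppc$p0, 0.8)
  expect_gt(ppc$p1, 0.2); expect_lt(ppc$p1, 0.8)

  # inflate the data noise tenfold: discrepancy of observed data explodes
  noisy <- st$panel
  set.seed(54)
  noisy$X0 <- noisy$X0 + rnorm(length(noisy$X0), 0, 4 * 0.4)
  noisy$X1 <- noisy$X1 + rnorm(length(noisy$X1), 0, 4 * 0.25)
  ppc2 <- posterior_predictive_check(d, build_model(noisy, st$U))
  expect_lt(ppc2$p0, 0.05)
  expect_lt(ppc2$p1, 0.05)
})

test_that("a tight hierarchy prior pools site estimates toward the mean", {
  st <- small_study()
  m_loose <- build_model(st$panel, st$U, model_priors(hc_scale = 2.5))
  m_tight <- build_model(st$panel, st$U, model_priors(hc_scale = 0.01))
  d_loose <- fit_popdyn(m_loose, chains = 2, iterations = 1200,
                        burn_in = 400, thin = 4, seed = 8)
  d_tight <- fit_popdyn(m_tight, chains = 2, iterations = 1200,
                        burn_in = 400, thin = 4, seed = 8)
  spread <- function(d) {
    th <- posterior_median_params(d)$theta
    mean(apply(th, 2, sd))
  }
  expect_lt(spread(d_tight), spread(d_loose))
})
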