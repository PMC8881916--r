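alpha1_panel <- function(T = 11, x0 = 2) {
  # single site, constant area exp(1), all-observed panel whose X1 follows
  # the alpha1-only recursion exactly (so observed = projected)
  const_panel(x1 = x0 + 0.5 * (0:(T - 1)), x0 = rep(1, T))
}

test_that("projection follows the deterministic recursions", {
  T <- 11
  U <- zero_U(1, T)
  panel <- alpha1_panel(T)

  # all coefficients zero, constant S: theta constant at the initial value
  pr0 <- project_abundance(make_theta(1), panel, U)
  expect_equal(pr0$theta1[1, ], rep(panel$X1[1, 1], T))

  # alpha1-only: linear growth from the anchor
  pr <- project_abundance(make_theta(1, alpha1 = 0.5), panel, U,
                          focal = "alpha1")
  expect_equal(pr$theta1[1, ], 2 + 0.5 * (0:(T - 1)), tolerance = 1e-12)

  expect_error(project_abundance(make_theta(1), panel, U, focal = "nope"),
               class = "fishdyn_invalid_argument")
})

test_that("projection matches a hand-unrolled two-site oracle", {
  set.seed(61)
  n <- 2; T <- 6
  theta <- make_theta(n, alpha0 = c(-1, -2), beta0 = c(1.2, 0.8),
                      alpha1 = c(1.4, 1.6), beta1 = c(-1.8, -2.2),
                      delta1 = c(0.3, 0.5), g0_tmean = 0.2, g1_tvar = 0.1)
  X0 <- matrix(rnorm(n * T, 5, 0.5), n)
  X1 <- matrix(rnorm(n * T, 5, 0.5), n)
  S <- matrix(exp(runif(n * T, 5, 6)), n)
  U <- array(rnorm(4 * n * T, 0, 1), c(4, n, T))
  panel <- abundance_panel(X0, X1, S)
  lS <- log(S)

  pr <- project_abundance(theta, panel, U, focal = "beta1")
  # hand unroll: beta1's predictor observed, everything else site-averaged
  for (i in 1:n) {
    rb1 <- X1[i, ] / lS[i, ]
    rd1_bar <- mean(X0[i, ] / lS[i, ])
    u_bar <- rowMeans(U[, i, ])
    g1 <- theta[i, c("g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2")]
    th <- X1[i, 1]
    expect_equal(pr$theta1[i, 1], th, tolerance = 1e-12)
    for (t in 2:T) {
      th <- theta[i, "alpha1"] + th + theta[i, "beta1"] * rb1[t - 1] +
        theta[i, "delta1"] * rd1_bar + sum(g1 * u_bar) +
        lS[i, t] - lS[i, t - 1]
      expect_equal(pr$theta1[i, t], unname(th), tolerance = 1e-10)
    }
  }
})

test_that("perturbation moves linear and quadratic temperature terms together", {
  set.seed(62)
  n <- 1; T <- 8
  theta <- make_theta(n, alpha0 = -1, beta0 = 1, g0_tmean = 0.3,
                      g0_tmean2 = -0.1)
  X0 <- matrix(rnorm(T, 5, 0.3), 1)
  X1 <- matrix(rnorm(T, 5, 0.3), 1)
  S <- matrix(400, 1, T)
  U <- array(rnorm(4 * T), c(4, 1, T))
  panel <- abundance_panel(X0, X1, S)

  per <- perturb_and_project(theta, panel, U, "tmean0")
  # linear-only perturbation differs from the joint one
  th_lin <- theta; th_lin[, "g0_tmean"] <- th_lin[, "g0_tmean"] * 1.1
  lin <- project_abundance(th_lin, panel, U, focal = "tmean0")
  expect_false(isTRUE(all.equal(per$theta0, lin$theta0)))
  # joint perturbation equals scaling both coefficients
  th_both <- theta
  th_both[, c("g0_tmean", "g0_tmean2")] <-
    th_both[, c("g0_tmean", "g0_tmean2")] * 1.1
  both <- project_abundance(th_both, panel, U, focal = "tmean0")
  expect_equal(per$theta0, both$theta0, tolerance = 1e-12)

  # perturbing a zero coefficient changes nothing
  pz <- perturb_and_project(make_theta(1, alpha1 = 0.5), alpha1_panel(8),
                            zero_U(1, 8), "beta1")
  oz <- project_abundance(make_theta(1, alpha1 = 0.5), alpha1_panel(8),
                          zero_U(1, 8), focal = "beta1")
  expect_identical(pz$theta1, oz$theta1)

  expect_error(perturb_and_project(theta, panel, U, "unknown"),
               class = "fishdyn_invalid_argument")
})

test_that("elasticity formula, exclusions and closed forms", {
  th <- matrix(c(1, 2, 4), 1)
  expect_equal(compute_elasticity(th, th), matrix(0, 1, 3),
               ignore_attr = TRUE)
  expect_error(compute_elasticity(th, th, perturb_fraction = 0),
               class = "fishdyn_invalid_argument")
  e <- compute_elasticity(matrix(c(1e-9, 2)), matrix(c(1, 2.2)))
  expect_true(is.na(e[1]) && attr(e, "n_excluded") == 1)

  # alpha1-only closed forms, via the full analysis machinery
  T <- 11; a1 <- 0.5
  for (x0 in c(0, a1, 2)) {
    panel <- const_panel(x1 = x0 + a1 * (0:(T - 1)), x0 = rep(1, T))
    el <- elasticity_analysis(make_theta(1, alpha1 = a1), panel,
                              zero_U(1, T), families = "alpha1")
    steps <- 1:(T - 1)
    want <- if (x0 == 0) rep(1, T - 1)
            else a1 * steps / (x0 + a1 * steps)
    expect_equal(unname(el$e$alpha1[1, -1]), want, tolerance = 1e-9)
  }
})

test_that("halving the perturbation barely changes smooth elasticities", {
  T <- 11
  panel <- const_panel(x1 = 3 + 0.4 * (0:(T - 1)), x0 = rep(2, T))
  th <- make_theta(1, alpha1 = 0.4)
  e10 <- elasticity_analysis(th, panel, zero_U(1, T),
                             families = "alpha1", perturb_fraction = 0.10)
  e05 <- elasticity_analysis(th, panel, zero_U(1, T),
                             families = "alpha1", perturb_fraction = 0.05)
  rel <- abs(e05$species_mean - e10$species_mean) / abs(e10$species_mean)
  expect_lt(rel, 0.01)
})

test_that("species mean is the mean of the site-years actually used", {
  sites <- generate_sites(8, seed = 71)
  truth <- simulation_truth(seed = 72)
  params <- generate_parameters(truth, sites)
  U <- generate_covariates(sites, 12, seed = 73)
  panel <- simulate_abundances(params, U, 500, 12, rep(4.5, 8),
                               truth$process_sds, seed = 74)
  el <- elasticity_analysis(as.matrix(params[, family_names()]), panel, U)
  for (f in names(el$e))
    expect_equal(el$species_mean[[f]], mean(el$e[[f]], na.rm = TRUE))
  expect_equal(rownames(el$site_mean), elasticity_families())
})

test_that("species comparisons test site-level elasticities pairwise", {
  fake_result <- function(vals, sites) {
    structure(list(site_mean = matrix(vals, 1,
                     dimnames = list("beta1", NULL)),
                   sites = sites, e = list()),
              class = "elasticity_result")
  }
  s <- sprintf("S%02d", 1:50)
  set.seed(81)
  v <- rnorm(50, 0, 0.1)
  a <- fake_result(v, s)
  b <- fake_result(v, s)                        # identical vectors
  c_ <- fake_result(v + 1, s)                   # shifted by 10 SDs

  out <- compare_species(list(A = a, B = b, C = c_))
  ab <- out[out$species_a == "A" & out$species_b == "B", ]
  expect_equal(ab$p_adj, 1)
  ac <- out[out$species_a == "A" & out$species_b == "C", ]
  expect_lt(ac$p_adj, 0.001)
  expect_true(all(out$test == "signed-rank"))

  # two shared sites only: skipped with a reason
  d <- fake_result(v[1:2], s[1:2])
  out2 <- compare_species(list(A = a, D = d))
  expect_equal(out2$test, "skipped")
  expect_match(out2$note, "shared sites")
})
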