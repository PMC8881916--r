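test_that("generate_sites respects bounds, determinism and argument checks", {
  s1 <- generate_sites(1, seed = 1)
  expect_equal(nrow(s1), 1L)
  expect_true(s1$elevation >= 0 && s1$elevation <= 1500)

  a <- generate_sites(50, seed = 7)
  b <- generate_sites(50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_sites(50, seed = 8)))

  expect_error(generate_sites(0), class = "fishdyn_invalid_argument")
})

test_that("generate_parameters reproduces the hyper-distribution", {
  sites <- generate_sites(1000, seed = 2)

  # degenerate normal: zero SD pins every site at the mean
  tr0 <- simulation_truth(hyper_means = c(alpha1 = 1.5),
                          hyper_sds = setNames(rep(0, 13), family_names()),
                          seed = 5)
  p0 <- generate_parameters(tr0, sites)
  expect_true(all(p0$alpha1 == 1.5))

  # Monte-Carlo check of the sampling SD
  tr <- simulation_truth(hyper_sds = c(beta0 = 0.3), seed = 11)
  p <- generate_parameters(tr, sites)
  expect_lt(abs(sd(p$beta0) - 0.3), 0.03)

  # deterministic linear gradient on the z-scored covariate
  trg <- simulation_truth(
    hyper_sds = setNames(rep(0, 13), family_names()),
    spatial_gradient = list(beta1 = list(covariate = "elevation",
                                         linear = -0.5)),
    seed = 3)
  pg <- generate_parameters(trg, sites)
  z <- (sites$elevation - mean(sites$elevation)) / sd(sites$elevation)
  expect_equal(unname(coef(lm(pg$beta1 ~ z))[2L]), -0.5, tolerance = 1e-12)

  expect_error(
    generate_parameters(simulation_truth(
      spatial_gradient = list(beta1 = list(covariate = "no_such",
                                           linear = 1))), sites),
    class = "fishdyn_invalid_argument")
  expect_error(
    simulation_truth(spatial_gradient = list(bogus = list(
      covariate = "elevation", linear = 1))),
    class = "fishdyn_invalid_argument")
})

test_that("simulate_abundances follows the deterministic recursions", {
  U <- zero_U(1, 10)
  base <- data.frame(site_id = "S001")
  mk <- function(...) {
    th <- as.data.frame(make_theta(1, ...))
    cbind(base, th)
  }

  # alpha-only >0+ recursion collapses to linear growth
  p <- simulate_abundances(mk(alpha1 = 0.4), U, areas = exp(1), T = 10,
                           x0 = 2, process_sds = c(0, 0), seed = 1)
  expect_equal(p$X1[1, ], 2 + 0.4 * (0:9), tolerance = 1e-12)

  # Gompertz fixed point X* = -alpha * log(S) / beta
  p2 <- simulate_abundances(mk(alpha1 = 1, beta1 = -0.5), U,
                            areas = exp(1), T = 10, x0 = 2,
                            process_sds = c(0, 0), seed = 1)
  expect_equal(p2$X1[1, ], rep(2, 10), tolerance = 1e-12)

  # linearity in U: gamma0 = 0.3 with U_tmean = +1 shifts X0 by 0.3
  U1 <- zero_U(1, 10); U1[1, , ] <- 1
  pa <- simulate_abundances(mk(alpha1 = 0.4, g0_tmean = 0.3), U1,
                            areas = exp(1), T = 10, x0 = 2,
                            process_sds = c(0, 0), seed = 1)
  pb <- simulate_abundances(mk(alpha1 = 0.4, g0_tmean = 0.3), U,
                            areas = exp(1), T = 10, x0 = 2,
                            process_sds = c(0, 0), seed = 1)
  expect_equal(pa$X0[1, ] - pb$X0[1, ], rep(0.3, 10), tolerance = 1e-12)

  expect_error(simulate_abundances(mk(), U, areas = 1, T = 10, x0 = 2),
               class = "fishdyn_invalid_argument")
  expect_error(simulate_abundances(mk(), U, areas = exp(1), T = 1, x0 = 2),
               class = "fishdyn_invalid_argument")
})

test_that("simulated dynamics reach the analytic Gompertz fixed point", {
  # with all gamma = 0 the long-run mean equals -alpha * log(S) / beta
  n_steps <- 10000
  th <- cbind(data.frame(site_id = "S001"),
              as.data.frame(make_theta(1, alpha1 = 1, beta1 = -0.5)))
  p <- simulate_abundances(th, zero_U(1, n_steps), areas = exp(2),
                           T = n_steps, x0 = 4,
                           process_sds = c(0, 0.3), seed = 42)
  fp <- -1 * log(exp(2)) / -0.5
  expect_lt(abs(mean(p$X1[1, -(1:100)]) - fp), 0.05)
})

test_that("simulate_lengths draws the stated mixture with labels", {
  one <- simulate_lengths(data.frame(n0 = 0, n1 = 5), seed = 1)
  expect_equal(nrow(one), 5L)
  expect_true(all(one$true_class == ">0+"))

  big <- simulate_lengths(data.frame(n0 = 10000, n1 = 10000), seed = 2)
  expect_lt(abs(mean(big$length_mm[big$true_class == "0+"]) - 60), 0.5)
  expect_lt(abs(mean(big$length_mm[big$true_class == ">0+"]) - 180), 0.5)
  expect_true(all(big$length_mm > 0))

  expect_error(simulate_lengths(data.frame(n0 = 5, n1 = 5),
                                list(mean0 = 200, sd0 = 10,
                                     mean1 = 100, sd1 = 10)),
               class = "fishdyn_invalid_argument")
  expect_error(simulate_lengths(data.frame(n0 = -1, n1 = 5)),
               class = "fishdyn_invalid_argument")
})

test_that("inject_missingness respects gap constraints and anchors", {
  sites <- generate_sites(200, seed = 3)
  truth <- simulation_truth(seed = 4)
  params <- generate_parameters(truth, sites)
  U <- generate_covariates(sites, 20, seed = 5)
  panel <- simulate_abundances(params, U, areas = 400, T = 20,
                               x0 = rep(4.5, 200),
                               process_sds = truth$process_sds, seed = 6)

  expect_identical(inject_missingness(panel, 0)$mask, panel$mask)

  pm <- inject_missingness(panel, 0.15, max_consecutive = 3, seed = 7)
  runs <- apply(!pm$mask, 1L, function(z) {
    r <- rle(z); max(c(0, r$lengths[r$values]))
  })
  expect_true(all(runs <= 3))                    # exhaustive run scan
  expect_true(all(pm$mask[, 1L]) && all(pm$mask[, 20L]))
  expect_gt(mean(!pm$mask), 0.14)

  # infeasible request: constraints reported, not silently ignored
  expect_warning(inject_missingness(panel, 0.99, seed = 8), "allowed only")
  expect_warning(inject_missingness(panel, 0.6, max_consecutive = 1,
                                    seed = 8),
                 "allowed only")
  expect_error(inject_missingness(panel, 1),
               class = "fishdyn_invalid_argument")
})

test_that("default synthetic panels pass the eligibility filters end-to-end", {
  sites <- generate_sites(30, seed = 9)
  truth <- simulation_truth(seed = 10)
  params <- generate_parameters(truth, sites)
  U <- generate_covariates(sites, 20, seed = 11)
  panel <- simulate_abundances(params, U, areas = 500, T = 20,
                               x0 = rep(4.5, 30),
                               process_sds = truth$process_sds, seed = 12)
  panel <- inject_missingness(panel, 0.08, 3, seed = 13)
  flt <- filter_time_series(panel_to_series(panel))
  expect_identical(sort(flt$retained), sort(panel$sites))
})

test_that("generators are bit-reproducible and leave the RNG untouched", {
  set.seed(99); before <- .Random.seed
  s <- generate_sites(10, seed = 1)
  expect_identical(.Random.seed, before)
  tr <- simulation_truth(seed = 2)
  p1 <- generate_parameters(tr, s)
  p2 <- generate_parameters(tr, s)
  expect_identical(p1, p2)
  U <- generate_covariates(s, 5, seed = 3)
  a1 <- simulate_abundances(p1, U, 300, 5, 4, c(0.3, 0.2), seed = 4)
  a2 <- simulate_abundances(p1, U, 300, 5, 4, c(0.3, 0.2), seed = 4)
  expect_identical(a1, a2)
  l1 <- simulate_lengths(data.frame(n0 = 10, n1 = 10), seed = 5)
  l2 <- simulate_lengths(data.frame(n0 = 10, n1 = 10), seed = 5)
  expect_identical(l1, l2)
})
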