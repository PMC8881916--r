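# Small in-code fixtures shared across test files.

# site coefficient matrix with named overrides, all other families zero
make_theta <- function(n, ...) {
  th <- matrix(0, n, 13, dimnames = list(NULL, family_names()))
  ov <- list(...)
  for (nm in names(ov)) th[, nm] <- ov[[nm]]
  th
}

zero_U <- function(n, T) array(0, c(4L, n, T),
                               dimnames = list(c("tmean", "tmean2",
                                                 "tvar", "tvar2"),
                                               NULL, NULL))

# deterministic single-site panel with constant area exp(1) (log S = 1)
const_panel <- function(x1, x0 = NULL, area = exp(1)) {
  T <- length(x1)
  if (is.null(x0)) x0 <- rep(0, T)
  abundance_panel(X0 = matrix(x0, 1L), X1 = matrix(x1, 1L),
                  S = matrix(area, 1L, T))
}

# naive term-by-term recomputation of both dynamic equations (independent
# of compute_lambda's vectorized path)
naive_lambda <- function(theta, X0, X1, logS, U) {
  n <- nrow(X1); T <- ncol(X1)
  l0 <- l1 <- matrix(NA_real_, n, T)
  for (i in 1:n) for (t in 1:T) {
    acc <- theta[i, "alpha0"] + theta[i, "beta0"] * X1[i, t] / logS[i, t] +
      logS[i, t]
    g <- c("g0_tmean", "g0_tmean2", "g0_tvar", "g0_tvar2")
    for (j in 1:4) acc <- acc + theta[i, g[j]] * U[j, i, t]
    l0[i, t] <- acc
    if (t >= 2) {
      acc <- theta[i, "alpha1"] + X1[i, t - 1] +
        theta[i, "beta1"] * X1[i, t - 1] / logS[i, t - 1] +
        theta[i, "delta1"] * X0[i, t - 1] / logS[i, t - 1] +
        logS[i, t] - logS[i, t - 1]
      g <- c("g1_tmean", "g1_tmean2", "g1_tvar", "g1_tvar2")
      for (j in 1:4) acc <- acc + theta[i, g[j]] * U[j, i, t]
      l1[i, t] <- acc
    }
  }
  list(lambda0 = l0, lambda1 = l1)
}

# labeled individuals from well-separated synthetic length mixtures,
# for classifier tests: features length, event size, degree-days
make_labeled_events <- function(n_events = 20, seed = 1,
                                mean0 = 60, sd0 = 10,
                                mean1 = 180, sd1 = 30) {
  counts <- data.frame(event_id = sprintf("E%03d", seq_len(n_events)),
                       n0 = 30 + (seq_len(n_events) * 7) %% 90,
                       n1 = 25 + (seq_len(n_events) * 11) %% 110)
  ind <- simulate_lengths(counts, list(mean0 = mean0, sd0 = sd0,
                                       mean1 = mean1, sd1 = sd1),
                          seed = seed)
  sz <- table(ind$event_id)
  dd <- stats::setNames(800 + 40 * seq_len(n_events) %% 13, counts$event_id)
  data.frame(event_id = ind$event_id,
             length_mm = ind$length_mm,
             n_event = as.integer(sz[ind$event_id]),
             degree_days = as.numeric(dd[ind$event_id]),
             class = ind$true_class)
}
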