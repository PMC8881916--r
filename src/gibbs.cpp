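// Gibbs sampler for the hierarchical two-size-class Gompertz model.
//
// Conditional structure exploited:
//  * per-site coefficient blocks (6 for the 0+ equation, 7 for the >0+
//    equation) are multivariate-normal given everything else;
//  * family means are normal given site coefficients and family SDs;
//  * family SDs and the two process SDs have half-Cauchy priors and are
//    updated by univariate slice sampling;
//  * masked log-abundances inside a site's series are latent normal nodes.
//
// All randomness goes through R's RNG so set.seed() in R makes a chain
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NF0 = 6; // alpha0, beta0, g0[4]
static const int NF1 = 7; // alpha1, beta1, delta1, g1[4]

// draw from N(Prec^{-1} b, Prec^{-1})
static vec rmvnorm_prec(const mat& Prec, const vec& b) {
  mat L;
  if (!chol(L, Prec, "lower")) {
    mat P2 = Prec + eye(Prec.n_rows, Prec.n_rows) * 1e-8;
    if (!chol(L, P2, "lower"))
      Rcpp::stop("precision matrix not positive definite");
  }
  vec m = solve(trimatl(L), b);
  m = solve(trimatu(L.t()), m);
  vec z(b.n_elem);
  for (uword k = 0; k < z.n_elem; ++k) z[k] = norm_rand();
  return m + solve(trimatu(L.t()), z);
}

// log target of an SD with half-Cauchy(A) prior given n_eff normal
// residual terms with sum of squares ss
static double sd_logf(double s, double n_eff, double ss, double A) {
  if (s <= 0.0) return -datum::inf;
  double r = s / A;
  return -n_eff * std::log(s) - ss / (2.0 * s * s) - std::log1p(r * r);
}

// univariate slice sampler on (0, inf) with stepping out
static double slice_sd(double x0, double n_eff, double ss, double A) {
  double f0 = sd_logf(x0, n_eff, ss, A);
  if (!std::isfinite(f0)) x0 = 1.0, f0 = sd_logf(x0, n_eff, ss, A);
  double y = f0 + std::log(unif_rand());
  double w = 0.5 * std::max(x0, 0.1);
  double L = x0 - w * unif_rand();
  double R = L + w;
  int m = 64;
  while (m-- > 0 && L > 1e-12 && sd_logf(L, n_eff, ss, A) > y) L -= w;
  if (L < 1e-12) L = 1e-12;
  m = 64;
  while (m-- > 0 && sd_logf(R, n_eff, ss, A) > y) R += w;
  for (int k = 0; k < 128; ++k) {
    double x1 = L + unif_rand() * (R - L);
    if (sd_logf(x1, n_eff, ss, A) > y) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// [[Rcpp::export]]
arma::mat gibbs_popdyn_cpp(arma::mat X0, arma::mat X1,
                           const arma::imat& O, const arma::imat& P,
                           const arma::mat& logS, const arma::cube& U,
                           double mu_sd, double hc_scale,
                           int iterations, int burn_in, int thin,
                           arma::vec mu, arma::vec sigma,
                           double sd0, double sd1) {
  const int n = X1.n_rows, T = X1.n_cols;
  const int n_kept = (iterations - burn_in) / thin;
  const int NC = 13 + 13 + 2 + 13 * n;
  mat out(n_kept, NC);

  mat th0(n, NF0), th1(n, NF1);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < NF0; ++j) th0(i, j) = mu[j];
    for (int j = 0; j < NF1; ++j) th1(i, j) = mu[6 + j];
  }

  // row builders ------------------------------------------------------
  auto z0row = [&](int i, int t, vec& z) {
    z[0] = 1.0;
    z[1] = X1(i, t) / logS(i, t);
    for (int j = 0; j < 4; ++j) z[2 + j] = U(i, t, j);
  };
  auto z1row = [&](int i, int t, vec& z) { // t >= 1
    z[0] = 1.0;
    z[1] = X1(i, t - 1) / logS(i, t - 1);
    z[2] = X0(i, t - 1) / logS(i, t - 1);
    for (int j = 0; j < 4; ++j) z[3 + j] = U(i, t, j);
  };
  auto y0 = [&](int i, int t) { return X0(i, t) - logS(i, t); };
  auto y1 = [&](int i, int t) {
    return X1(i, t) - X1(i, t - 1) - (logS(i, t) - logS(i, t - 1));
  };
  auto lam0 = [&](int i, int t) {
    double v = th0(i, 0) + th0(i, 1) * X1(i, t) / logS(i, t) + logS(i, t);
    for (int j = 0; j < 4; ++j) v += th0(i, 2 + j) * U(i, t, j);
    return v;
  };
  auto lam1 = [&](int i, int t) { // t >= 1
    double v = th1(i, 0) + X1(i, t - 1) +
      th1(i, 1) * X1(i, t - 1) / logS(i, t - 1) +
      th1(i, 2) * X0(i, t - 1) / logS(i, t - 1) +
      logS(i, t) - logS(i, t - 1);
    for (int j = 0; j < 4; ++j) v += th1(i, 3 + j) * U(i, t, j);
    return v;
  };

  vec z6(NF0), z7(NF1);
  int kept = 0;

  for (int iter = 0; iter < iterations; ++iter) {
    double prec0 = 1.0 / (sd0 * sd0), prec1 = 1.0 / (sd1 * sd1);

    // --- site coefficient blocks ------------------------------------
    for (int i = 0; i < n; ++i) {
      mat A0(NF0, NF0, fill::zeros);
      vec b0(NF0, fill::zeros);
      for (int t = 0; t < T; ++t) {
        if (!P(i, t)) continue;
        z0row(i, t, z6);
        A0 += prec0 * (z6 * z6.t());
        b0 += prec0 * y0(i, t) * z6;
      }
      for (int j = 0; j < NF0; ++j) {
        double pf = 1.0 / (sigma[j] * sigma[j]);
        A0(j, j) += pf;
        b0[j] += pf * mu[j];
      }
      th0.row(i) = rmvnorm_prec(A0, b0).t();

      mat A1(NF1, NF1, fill::zeros);
      vec b1(NF1, fill::zeros);
      for (int t = 1; t < T; ++t) {
        if (!P(i, t) || !P(i, t - 1)) continue;
        z1row(i, t, z7);
        A1 += prec1 * (z7 * z7.t());
        b1 += prec1 * y1(i, t) * z7;
      }
      for (int j = 0; j < NF1; ++j) {
        double pf = 1.0 / (sigma[6 + j] * sigma[6 + j]);
        A1(j, j) += pf;
        b1[j] += pf * mu[6 + j];
      }
      th1.row(i) = rmvnorm_prec(A1, b1).t();
    }

    // --- family means and SDs ---------------------------------------
    for (int f = 0; f < 13; ++f) {
      const bool is0 = f < 6;
      const int j = is0 ? f : f - 6;
      double s2 = sigma[f] * sigma[f];
      double sum = 0.0;
      for (int i = 0; i < n; ++i) sum += is0 ? th0(i, j) : th1(i, j);
      double prec = n / s2 + 1.0 / (mu_sd * mu_sd);
      double mean = (sum / s2) / prec;
      mu[f] = mean + norm_rand() / std::sqrt(prec);

      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = (is0 ? th0(i, j) : th1(i, j)) - mu[f];
        ss += d * d;
      }
      sigma[f] = slice_sd(sigma[f], (double)n, ss, hc_scale);
    }

    // --- process SDs -------------------------------------------------
    double rss0 = 0.0, rss1 = 0.0;
    long n0 = 0, n1 = 0;
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < T; ++t) {
        if (!P(i, t)) continue;
        double r = X0(i, t) - lam0(i, t);
        rss0 += r * r; ++n0;
        if (t >= 1 && P(i, t - 1)) {
          double r1 = X1(i, t) - lam1(i, t);
          rss1 += r1 * r1; ++n1;
        }
      }
    }
    sd0 = slice_sd(sd0, (double)n0, rss0, hc_scale);
    sd1 = slice_sd(sd1, (double)n1, rss1, hc_scale);

    // --- latent (masked) log-abundances ------------------------------
    prec0 = 1.0 / (sd0 * sd0);
    prec1 = 1.0 / (sd1 * sd1);
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < T; ++t) {
        if (!P(i, t) || O(i, t)) continue;

        // X0(i,t): own equation + next-year >0+ equation
        {
          double prec = prec0, num = lam0(i, t) * prec0;
          if (t + 1 < T && P(i, t + 1)) {
            double c = th1(i, 2) / logS(i, t);
            double a = lam1(i, t + 1) - c * X0(i, t); // remove current value
            num += c * (X1(i, t + 1) - a) * prec1;
            prec += c * c * prec1;
          }
          X0(i, t) = num / prec + norm_rand() / std::sqrt(prec);
        }

        // X1(i,t): own equation + next-year >0+ equation + same-year 0+
        {
          double prec = 0.0, num = 0.0;
          bool anchored = false;
          if (t >= 1 && P(i, t - 1)) {
            num += lam1(i, t) * prec1;
            prec += prec1;
            anchored = true;
          }
          if (t + 1 < T && P(i, t + 1)) {
            double k = 1.0 + th1(i, 1) / logS(i, t);
            double B = lam1(i, t + 1) - k * X1(i, t);
            num += k * (X1(i, t + 1) - B) * prec1;
            prec += k * k * prec1;
          }
          {
            double m = th0(i, 1) / logS(i, t);
            double C = lam0(i, t) - m * X1(i, t);
            num += m * (X0(i, t) - C) * prec0;
            prec += m * m * prec0;
          }
          if (!anchored) { // diffuse prior on an unanchored initial state
            prec += 0.01;
          }
          X1(i, t) = num / prec + norm_rand() / std::sqrt(prec);
        }
      }
    }

    // --- record -------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == thin - 1) {
      if (kept < n_kept) {
        int c = 0;
        for (int f = 0; f < 13; ++f) out(kept, c++) = mu[f];
        for (int f = 0; f < 13; ++f) out(kept, c++) = sigma[f];
        out(kept, c++) = sd0;
        out(kept, c++) = sd1;
        for (int j = 0; j < NF0; ++j)
          for (int i = 0; i < n; ++i) out(kept, c++) = th0(i, j);
        for (int j = 0; j < NF1; ++j)
          for (int i = 0; i < n; ++i) out(kept, c++) = th1(i, j);
        ++kept;
      }
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out.rows(0, kept - 1);
}
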