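## Size-class discrimination from length-frequency histograms.
##
## Each sampling event's body lengths are modelled as a mixture of two
## normal components (0+ and >0+ fish); the class boundary is the length
## where the two weighted component densities cross.  Because the mixture
## fit is unreliable on events without clear bimodality, a probabilistic
## classifier is calibrated on a small set of clearly separated events and
## used to predict individual status elsewhere, validated by repeated
## split-sample cross-validation scored with Cohen's kappa.

#' Fit a two-component normal mixture to body lengths by EM
#'
#' Expectation-maximization on a two-normal mixture with components
#' ordered by mean.  Initialization is a deterministic 2-means split
#' seeded at the 25% and 75% length quantiles, so the fit is reproducible
#' without consuming RNG state.
#'
#' @param lengths numeric body lengths (mm).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param min_n minimum number of lengths required.
#' @return object of class `mixture_fit`: `weights`, `means`, `sds`,
#'   `boundary` (crossing point, `NA` if none exists), `loglik`,
#'   `converged`, `n_iter`, `n`.
#' @export
fit_length_mixture <- function(lengths, max_iter = 500, tol = 1e-8,
                               min_n = 10) {
  lengths <- lengths[is.finite(lengths)]
  n <- length(lengths)
  if (n < min_n)
    stop(errorCondition(
      sprintf("need at least %d lengths, got %d", min_n, n),
      class = c("fishdyn_insufficient_data", "error")))
  if (length(unique(lengths)) < 2L)
    stop(errorCondition("all lengths identical: mixture fit is degenerate",
                        class = c("fishdyn_degenerate_fit", "error")))

  centers <- quantile(lengths, c(0.25, 0.75), names = FALSE)
  if (centers[1L] == centers[2L]) centers <- range(lengths)
  km <- kmeans(lengths, centers = matrix(centers, 2L), algorithm = "Lloyd",
               iter.max = 50)
  grp <- if (km$centers[1L] <= km$centers[2L]) km$cluster else 3L - km$cluster
  w <- tabulate(grp, 2L) / n
  mu <- tapply(lengths, grp, mean)
  s2 <- tapply(lengths, grp, function(x) max(var(x), 1e-4))
  s2[is.na(s2)] <- var(lengths)

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * dnorm(lengths, mu[1L], sqrt(s2[1L]))
    d2 <- w[2L] * dnorm(lengths, mu[2L], sqrt(s2[2L]))
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot)))
      stop(errorCondition("EM collapsed to a degenerate component",
                          class = c("fishdyn_degenerate_fit", "error")))
    r <- d1 / tot
    ll <- sum(log(tot))
    w <- c(mean(r), mean(1 - r))
    if (min(w) < 1e-8)
      stop(errorCondition("a mixture component vanished during EM",
                          class = c("fishdyn_degenerate_fit", "error")))
    mu <- c(sum(r * lengths) / sum(r),
            sum((1 - r) * lengths) / sum(1 - r))
    s2 <- c(sum(r * (lengths - mu[1L])^2) / sum(r),
            sum((1 - r) * (lengths - mu[2L])^2) / sum(1 - r))
    if (any(s2 < 1e-8))
      stop(errorCondition("a component collapsed onto a point",
                          class = c("fishdyn_degenerate_fit", "error")))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (mu[1L] > mu[2L]) { # order components by mean
    mu <- rev(mu); s2 <- rev(s2); w <- rev(w)
  }
  fit <- structure(list(weights = as.numeric(w), means = as.numeric(mu),
                        sds = sqrt(as.numeric(s2)), loglik = ll,
                        converged = converged, n_iter = it, n = n),
                   class = "mixture_fit")
  fit$boundary <- tryCatch(crossing_boundary(fit), error = function(e) NA_real_)
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component normal length mixture (n =", x$n, ")\n")
  cat(sprintf("  0+ : w = %.3f, mean = %.1f mm, sd = %.1f mm\n",
              x$weights[1L], x$means[1L], x$sds[1L]))
  cat(sprintf("  >0+: w = %.3f, mean = %.1f mm, sd = %.1f mm\n",
              x$weights[2L], x$means[2L], x$sds[2L]))
  cat(sprintf("  boundary = %.2f mm, logLik = %.2f, %s after %d iterations\n",
              x$boundary, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Length at which two weighted normal densities cross
#'
#' Solves `w1 * phi(x; m1, s1) = w2 * phi(x; m2, s2)` for the root lying
#' between the two component means: the size-class boundary.  The equation
#' is quadratic in `x` and solved in closed form; a numeric root finder is
#' the fallback for ill-conditioned cases.  With equal SDs the boundary is
#' the midpoint shifted by `s^2 * log(w1/w2) / (m2 - m1)`.
#'
#' @param fit a `mixture_fit`, or a list with `weights`, `means`, `sds`.
#' @return boundary length (mm).
#' @export
crossing_boundary <- function(fit) {
  w <- fit$weights; m <- fit$means; s <- fit$sds
  if (!isTRUE(m[1L] != m[2L]))
    stop(errorCondition("component means are equal: no boundary",
                        class = c("fishdyn_no_boundary", "error")))
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  a <- 1 / (2 * s[2L]^2) - 1 / (2 * s[1L]^2)
  b <- m[1L] / s[1L]^2 - m[2L] / s[2L]^2
  c0 <- m[2L]^2 / (2 * s[2L]^2) - m[1L]^2 / (2 * s[1L]^2) +
    log(w[1L] / w[2L]) + log(s[2L] / s[1L])
  lo <- min(m); hi <- max(m)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots > lo & roots < hi]
  if (!length(roots)) {
    # numeric fallback on the log-density difference
    f <- function(x) dnorm(x, m[1L], s[1L], log = TRUE) + log(w[1L]) -
      dnorm(x, m[2L], s[2L], log = TRUE) - log(w[2L])
    if (sign(f(lo + 1e-9)) * sign(f(hi - 1e-9)) < 0)
      roots <- uniroot(f, c(lo + 1e-9, hi - 1e-9), tol = 1e-12)$root
  }
  if (!length(roots))
    stop(errorCondition("densities do not cross between the component means",
                        class = c("fishdyn_no_boundary", "error")))
  min(roots)
}

#' Cumulative degree-days above a growth threshold
#'
#' Sum over days of `max(0, temperature - threshold)`; 12 degrees C is the
#' conventional threshold below which growth of temperate cyprinids is
#' assumed inhibited.
#'
#' @param daily_temps numeric daily water temperatures (degrees C).
#' @param threshold threshold temperature.
#' @return non-negative degree-day sum.
#' @export
degree_days <- function(daily_temps, threshold = 12) {
  daily_temps <- daily_temps[is.finite(daily_temps)]
  if (!length(daily_temps)) stop_invalid("temperature series is empty")
  sum(pmax(0, daily_temps - threshold))
}

#' Train a probabilistic 0+/>0+ status classifier
#'
#' Models individual status as a function of body length, the number of
#' individuals in the sampling event (a density-dependence proxy) and the
#' annual cumulative degree-days above 12 degrees C.  The default family
#' is a logistic regression; `family = "gam"` uses a thin-plate smooth of
#' length (requires mgcv).  Any probabilistic classifier over these three
#' features is conformant; the workflow, not the learner, is what matters.
#'
#' @param labeled data frame with columns `length_mm`, `n_event`,
#'   `degree_days`, `class` (factor with levels `0+`, `>0+`), and
#'   `event_id` identifying the calibration events.
#' @param family `"logistic"` (default) or `"gam"`.
#' @return object of class `status_classifier` with an `importance`
#'   element (absolute standardized coefficients).
#' @export
train_status_classifier <- function(labeled,
                                    family = c("logistic", "gam")) {
  family <- match.arg(family)
  need <- c("length_mm", "n_event", "degree_days", "class")
  if (!all(need %in% names(labeled)))
    stop_invalid(paste("labeled data must have columns",
                       paste(need, collapse = ", ")))
  labeled$class <- factor(labeled$class, levels = c("0+", ">0+"))
  if (nlevels(droplevels(labeled$class)) < 2L)
    stop_invalid("training data contain a single class")
  if (!is.null(labeled$event_id) &&
      length(unique(labeled$event_id)) < 2L)
    stop_invalid("need at least 2 labeled events")
  y <- as.integer(labeled$class == ">0+")
  if (family == "logistic") {
    model <- suppressWarnings(
      glm(y ~ length_mm + n_event + degree_days, data = labeled,
          family = binomial()))
    sds <- vapply(labeled[, c("length_mm", "n_event", "degree_days")],
                  sd, numeric(1))
    importance <- abs(coef(model)[-1L] * sds)
  } else {
    if (!requireNamespace("mgcv", quietly = TRUE))
      stop_invalid("family = 'gam' requires the mgcv package")
    model <- mgcv::gam(y ~ s(length_mm) + n_event + degree_days,
                       data = labeled, family = binomial())
    importance <- NULL
  }
  structure(list(model = model, family = family, importance = importance),
            class = "status_classifier")
}

#' Predict 0+/>0+ status
#'
#' @param object a `status_classifier`.
#' @param newdata data frame with `length_mm`, `n_event`, `degree_days`.
#' @param type `"class"` or `"prob"` (probability of >0+).
#' @param ... unused.
#' @export
predict.status_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- suppressWarnings(
    as.numeric(predict(object$model, newdata = newdata, type = "response")))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, ">0+", "0+"), levels = c("0+", ">0+"))
}

#' Cohen's kappa for predicted vs true class labels
#'
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed agreement and
#' `pe` the agreement expected by chance from the marginals.  Undefined
#' (returned as `NA` with a warning) when `pe = 1`, i.e. when truth and
#' prediction are each a single identical class.
#'
#' @param truth,pred factors or vectors of equal length.
#' @return kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(truth, pred) {
  lev <- union(unique(as.character(truth)), unique(as.character(pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  tab <- table(truth, pred)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("kappa undefined: chance agreement equals 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Split-sample cross-validation scored by Cohen's kappa
#'
#' Repeats `n_splits` times: hold out a fraction of the labeled
#' *events*, train the status classifier on the rest, score kappa between
#' true and predicted classes on the held-out individuals.  Splits with a
#' single-class holdout yield `NA` with a warning.
#'
#' @param labeled labeled individuals (see [train_status_classifier()]);
#'   must carry `event_id`.
#' @param n_splits number of random splits (>= 1).
#' @param holdout fraction of events held out per split.
#' @param seed integer seed.
#' @param family classifier family.
#' @return list with `kappa` (per split), `mean`, `sd`, `n_na`.
#' @export
cross_validate_kappa <- function(labeled, n_splits = 100, holdout = 0.3,
                                 seed = 1L, family = "logistic") {
  if (n_splits < 1) stop_invalid("n_splits must be >= 1")
  if (is.null(labeled$event_id))
    stop_invalid("labeled data must carry event_id")
  events <- unique(labeled$event_id)
  n_hold <- max(1L, round(holdout * length(events)))
  if (n_hold >= length(events))
    stop_invalid("holdout fraction leaves no training events")
  with_seed(seed, {
    ks <- vapply(seq_len(n_splits), function(s) {
      hold <- sample(events, n_hold)
      train <- labeled[!labeled$event_id %in% hold, , drop = FALSE]
      test <- labeled[labeled$event_id %in% hold, , drop = FALSE]
      if (nlevels(droplevels(factor(train$class))) < 2L) return(NA_real_)
      clf <- train_status_classifier(train, family = family)
      pred <- predict(clf, test)
      if (nlevels(droplevels(factor(test$class))) < 2L &&
          nlevels(droplevels(pred)) < 2L) {
        warning("holdout contains a single class: kappa undefined for a split")
        return(NA_real_)
      }
      cohen_kappa(test$class, pred)
    }, numeric(1))
    list(kappa = ks, mean = mean(ks, na.rm = TRUE),
         sd = sd(ks, na.rm = TRUE), n_na = sum(is.na(ks)))
  })
}

#' Sum classified individuals into per-event size-class counts
#'
#' @param classified data frame with `event_id` and `class` (`0+`/`>0+`);
#'   every individual must be classified.
#' @param events optional vector of event ids to report (events with no
#'   individuals get counts of zero).
#' @return data frame `event_id`, `n0`, `n1`.
#' @export
aggregate_counts <- function(classified, events = NULL) {
  if (nrow(classified) > 0 && any(is.na(classified$class)))
    stop_invalid("unclassified individuals present")
  ids <- events %||% unique(classified$event_id)
  cl <- factor(classified$class, levels = c("0+", ">0+"))
  tab <- table(factor(classified$event_id, levels = ids), cl)
  data.frame(event_id = ids,
             n0 = as.integer(tab[, "0+"]),
             n1 = as.integer(tab[, ">0+"]))
}
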