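## Pipeline orchestration and format bridging.
##
## `run_pipeline()` executes the full analysis chain on synthetic or
## supplied data — simulate, split-sizes, covariates, filter, fit,
## elasticity, spatial — writing each stage's outputs and a manifest with
## seeds, input hashes, record counts and wall-clock so a run is
## reproducible from its configuration alone.

#' Pipeline configuration
#'
#' Thresholds default to the reference analysis values: series of at least
#' 15 sampled years with at least 50% non-null captures and no gap longer
#' than 3 years; 10% perturbation for elasticities; 3 chains of 11,000
#' iterations, 1,000 burn-in, thinning 10.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param n_sites,n_years synthetic study dimensions.
#' @param stages character subset of
#'   `c("simulate","split_sizes","covariates","filter","fit","elasticity","spatial")`.
#' @param sampler list `chains`, `iterations`, `burn_in`, `thin`.
#' @param filters list `min_years`, `min_nonnull`, `max_gap`.
#' @param perturb_fraction elasticity perturbation.
#' @param missing_fraction target fraction of masked site-years.
#' @param center geographic range center `c(lon, lat)`.
#' @param n_calibration number of clearly bimodal events used to calibrate
#'   the status classifier.
#' @param n_cv_splits split-sample cross-validation repetitions.
#' @param mixture_spec true length mixture for the generator.
#' @param zero_handling `"true_zero"` keeps sampled null captures as
#'   log(0 + 1) = 0; `"censored"` masks them as missing.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_sites = 30L, n_years = 20L,
                       stages = c("simulate", "split_sizes", "covariates",
                                  "filter", "fit", "elasticity", "spatial"),
                       sampler = list(chains = 3L, iterations = 11000L,
                                      burn_in = 1000L, thin = 10L),
                       filters = list(min_years = 15L, min_nonnull = 0.5,
                                      max_gap = 3L),
                       perturb_fraction = 0.10,
                       missing_fraction = 0.08,
                       center = c(2.5, 46.5),
                       n_calibration = 20L,
                       n_cv_splits = 100L,
                       mixture_spec = list(mean0 = 60, sd0 = 10,
                                           mean1 = 180, sd1 = 30),
                       zero_handling = c("true_zero", "censored")) {
  structure(list(seed = as.integer(seed), n_sites = n_sites,
                 n_years = n_years, stages = stages, sampler = sampler,
                 filters = filters, perturb_fraction = perturb_fraction,
                 missing_fraction = missing_fraction, center = center,
                 n_calibration = n_calibration, n_cv_splits = n_cv_splits,
                 mixture_spec = mixture_spec,
                 zero_handling = match.arg(zero_handling)),
            class = "run_config")
}

#' Convert per-event size-class counts to an abundance panel
#'
#' Log-abundance is `log(count + 1)`, so sampled null captures stay on the
#' log scale (`zero_handling = "true_zero"`); alternatively null captures
#' are treated as censored and masked.
#'
#' @param counts data frame `site_id`, `year`, `n0`, `n1`, `area_m2`.
#' @param sites ordered site ids defining panel rows.
#' @param years ordered years defining panel columns.
#' @param zero_handling see [run_config()].
#' @return an `abundance_panel`.
#' @export
counts_to_panel <- function(counts, sites, years,
                            zero_handling = "true_zero") {
  n <- length(sites); T <- length(years)
  X0 <- X1 <- S <- matrix(NA_real_, n, T)
  mask <- matrix(FALSE, n, T)
  i <- match(counts$site_id, sites)
  t <- match(counts$year, years)
  X0[cbind(i, t)] <- log(counts$n0 + 1)
  X1[cbind(i, t)] <- log(counts$n1 + 1)
  S[cbind(i, t)] <- counts$area_m2
  mask[cbind(i, t)] <- TRUE
  if (zero_handling == "censored")
    mask[cbind(i, t)] <- mask[cbind(i, t)] & (counts$n0 + counts$n1 > 0)
  # areas must be defined wherever the model needs an offset
  for (r in seq_len(n)) {
    s <- S[r, ]
    if (all(is.na(s))) next
    s[is.na(s)] <- mean(s, na.rm = TRUE)
    S[r, ] <- s
  }
  abundance_panel(X0, X1, S, mask, sites, years)
}

seed_for <- function(config, stage) {
  offsets <- c(simulate = 11L, split_sizes = 23L, covariates = 31L,
               filter = 41L, fit = 53L, elasticity = 61L, spatial = 71L)
  config$seed * 100L + offsets[[stage]]
}

write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

#' Run the analysis pipeline
#'
#' Executes the enabled stages in their canonical order, writing per-stage
#' outputs under `out_dir` plus `manifest.json`.  A stage whose upstream
#' results are unavailable raises a dependency error.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `results` (in-memory stage products) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("fishdyn_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  canonical <- c("simulate", "split_sizes", "covariates", "filter", "fit",
                 "elasticity", "spatial")
  stages <- canonical[canonical %in% config$stages]
  needs <- list(split_sizes = "simulate", covariates = "simulate",
                filter = c("split_sizes", "covariates"),
                fit = "filter", elasticity = "fit", spatial = "elasticity")
  res <- list()
  manifest <- list(config = unclass(config), stages = list())

  log_stage <- function(name, t0, files, records) {
    manifest$stages[[name]] <<- list(
      stage = name, seed = seed_for(config, name),
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      records = records,
      outputs = lapply(files, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  }

  for (st in stages) {
    for (dep in needs[[st]])
      if (!dep %in% stages)
        stop_invalid(sprintf("stage '%s' needs stage '%s' to be enabled",
                             st, dep))
    t0 <- as.numeric(Sys.time())
    if (st == "simulate") {
      s <- seed_for(config, st)
      sites <- generate_sites(config$n_sites, seed = s)
      truth <- simulation_truth(seed = s + 1L)
      params <- generate_parameters(truth, sites)
      years <- seq(1991L, length.out = config$n_years)
      daily <- generate_daily_temperatures(sites, years, seed = s + 2L)
      events <- data.frame(site_id = rep(sites$site_id, length(years)),
                           date = as.Date(paste0(rep(years,
                             each = nrow(sites)), "-09-15")))
      tsum <- summarize_temperature(daily, events)
      U <- build_U(tsum)
      areas <- matrix(with_seed(s + 3L,
                                exp(rnorm(config$n_sites, log(500), 0.3))),
                      config$n_sites, config$n_years)
      x0 <- with_seed(s + 4L, rnorm(config$n_sites, 4.5, 0.5))
      panel <- simulate_abundances(params, U, areas, config$n_years, x0,
                                   truth$process_sds, seed = s + 5L)
      panel$years <- years
      panel <- inject_missingness(panel, config$missing_fraction,
                                  config$filters$max_gap, seed = s + 6L)
      obs <- which(panel$mask, arr.ind = TRUE)
      counts <- data.frame(
        site_id = panel$sites[obs[, 1L]],
        year = panel$years[obs[, 2L]],
        n0 = pmax(0L, as.integer(round(exp(panel$X0[obs]) - 1))),
        n1 = pmax(0L, as.integer(round(exp(panel$X1[obs]) - 1))),
        area_m2 = panel$S[obs])
      counts$event_id <- paste(counts$site_id, counts$year, sep = "_")
      lengths <- simulate_lengths(counts, config$mixture_spec,
                                  seed = s + 7L)
      # degree-days above 12 C over the year preceding each event
      dd <- vapply(seq_len(nrow(counts)), function(k) {
        w <- daily[daily$site_id == counts$site_id[k], ]
        end <- as.Date(paste0(counts$year[k], "-09-15"))
        degree_days(w$temp_c[w$date > end - 365 & w$date <= end])
      }, numeric(1))
      counts$degree_days <- dd
      res$simulate <- list(sites = sites, truth = truth, params = params,
                           daily = daily, panel_true = panel,
                           counts = counts, lengths = lengths, U_true = U)
      f1 <- file.path(out_dir, "sites.csv")
      write.csv(sites, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "abundance_true.csv")
      write.csv(counts, f2, row.names = FALSE)
      f3 <- file.path(out_dir, "truth.json")
      write_json(list(hyper_means = as.list(truth$hyper_means),
                      hyper_sds = as.list(truth$hyper_sds),
                      process_sds = as.list(truth$process_sds),
                      seed = truth$seed), f3)
      log_stage(st, t0, list(f1, f2, f3),
                c(sites = nrow(sites), events = nrow(counts),
                  individuals = nrow(lengths)))
    } else if (st == "split_sizes") {
      sim <- res$simulate
      s <- seed_for(config, st)
      counts <- sim$counts
      lengths <- sim$lengths
      n_event <- table(lengths$event_id)
      ev_sizes <- as.integer(n_event[counts$event_id])
      calib <- counts$event_id[order(-ev_sizes)][
        seq_len(min(config$n_calibration, nrow(counts)))]
      labeled <- NULL
      for (ev in calib) {
        lx <- lengths$length_mm[lengths$event_id == ev]
        fit <- tryCatch(fit_length_mixture(lx), error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$boundary)) next
        labeled <- rbind(labeled, data.frame(
          event_id = ev, length_mm = lx,
          n_event = length(lx),
          degree_days = counts$degree_days[counts$event_id == ev],
          class = factor(ifelse(lx < fit$boundary, "0+", ">0+"),
                         levels = c("0+", ">0+"))))
      }
      clf <- train_status_classifier(labeled)
      cv <- cross_validate_kappa(labeled, n_splits = config$n_cv_splits,
                                 seed = s)
      all_ind <- data.frame(
        event_id = lengths$event_id, length_mm = lengths$length_mm,
        n_event = as.integer(n_event[lengths$event_id]),
        degree_days = counts$degree_days[match(lengths$event_id,
                                               counts$event_id)])
      all_ind$class <- predict(clf, all_ind)
      est <- aggregate_counts(all_ind, events = counts$event_id)
      est$site_id <- counts$site_id
      est$year <- counts$year
      est$area_m2 <- counts$area_m2
      res$split_sizes <- list(classifier = clf, cv = cv,
                              counts_est = est, calibration = calib)
      f1 <- file.path(out_dir, "abundance_estimated.csv")
      write.csv(est, f1, row.names = FALSE)
      log_stage(st, t0, list(f1),
                c(events = nrow(est), mean_kappa = cv$mean))
    } else if (st == "covariates") {
      sim <- res$simulate
      events <- data.frame(site_id = rep(sim$sites$site_id,
                                         config$n_years),
                           date = as.Date(paste0(rep(sim$panel_true$years,
                             each = nrow(sim$sites)), "-09-15")))
      tsum <- summarize_temperature(sim$daily, events)
      U <- build_U(tsum)
      res$covariates <- list(U = U, summaries = tsum)
      f1 <- file.path(out_dir, "covariates.csv")
      write.csv(tsum, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "standardization.json")
      write_json(lapply(U$standardization, as.list), f2)
      log_stage(st, t0, list(f1, f2), c(site_years = nrow(tsum)))
    } else if (st == "filter") {
      est <- res$split_sizes$counts_est
      sim <- res$simulate
      grid <- expand.grid(site_id = sim$sites$site_id,
                          year = sim$panel_true$years,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$count <- (est$n0 + est$n1)[match(paste(grid$site_id, grid$year),
                                            paste(est$site_id, est$year))]
      flt <- filter_time_series(grid, config$filters$min_years,
                                config$filters$min_nonnull,
                                config$filters$max_gap)
      keep <- match(flt$retained, sim$sites$site_id)
      panel <- counts_to_panel(est[est$site_id %in% flt$retained, ],
                               sim$sites$site_id[keep],
                               sim$panel_true$years,
                               config$zero_handling)
      Uv <- res$covariates$U$values[, keep, , drop = FALSE]
      res$filter <- list(report = flt$report, panel = panel, U = Uv,
                         sites = sim$sites[keep, , drop = FALSE],
                         keep = keep)
      f1 <- file.path(out_dir, "filter_report.csv")
      write.csv(flt$report, f1, row.names = FALSE)
      log_stage(st, t0, list(f1),
                c(retained = length(flt$retained),
                  rejected = sum(!flt$report$retained)))
    } else if (st == "fit") {
      flt <- res$filter
      model <- build_model(flt$panel, flt$U)
      draws <- fit_popdyn(model, chains = config$sampler$chains,
                          iterations = config$sampler$iterations,
                          burn_in = config$sampler$burn_in,
                          thin = config$sampler$thin,
                          seed = seed_for(config, st))
      summ <- summary(draws)
      ppc <- posterior_predictive_check(draws, model)
      res$fit <- list(model = model, draws = draws, summary = summ,
                      ppc = ppc)
      f1 <- file.path(out_dir, "posterior_summary.json")
      write_json(summ, f1)
      f2 <- file.path(out_dir, "ppc.json")
      write_json(ppc, f2)
      log_stage(st, t0, list(f1, f2),
                c(parameters = nrow(summ),
                  max_rhat = max(summ$rhat, na.rm = TRUE)))
    } else if (st == "elasticity") {
      med <- posterior_median_params(res$fit$draws)
      el <- elasticity_analysis(med$theta, res$filter$panel, res$filter$U,
                                perturb_fraction = config$perturb_fraction)
      res$elasticity <- el
      long <- do.call(rbind, lapply(names(el$e), function(f) {
        e <- el$e[[f]]
        idx <- which(is.finite(e), arr.ind = TRUE)
        data.frame(parameter = f, site_id = el$sites[idx[, 1L]],
                   year = res$filter$panel$years[idx[, 2L]],
                   value = e[idx])
      }))
      f1 <- file.path(out_dir, "elasticity.csv")
      write.csv(long, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "elasticity_species.json")
      write_json(as.list(el$species_mean), f2)
      log_stage(st, t0, list(f1, f2),
                c(site_years = nrow(long)))
    } else if (st == "spatial") {
      el <- res$elasticity
      sites <- res$filter$sites
      sites$distance <- distance_to_center(sites, config$center)
      fits <- lapply(rownames(el$site_mean), function(f)
        fit_candidates(data.frame(site_id = el$sites,
                                  value = el$site_mean[f, ]), sites))
      names(fits) <- rownames(el$site_mean)
      sel <- select_best(fits)
      res$spatial <- sel
      f1 <- file.path(out_dir, "model_selection.csv")
      write.csv(sel$table, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "model_coefficients.json")
      write_json(lapply(fits, function(r) as.list(r$coefficients)), f2)
      log_stage(st, t0, list(f1, f2),
                c(families = nrow(sel$table)))
    }
  }
  mf <- file.path(out_dir, "manifest.json")
  write_json(manifest, mf)
  invisible(list(results = res, manifest = manifest, dir = out_dir))
}

#' Import serialized model-input files
#'
#' Loads an RData/RDS file holding model-ready arrays (as distributed with
#' the reference study), discovers the variables by name and shape, and
#' maps them onto the package's containers.  The importer reports what it
#' found rather than hard-coding names: a 3-D numeric array with one
#' extent of 4 is taken as the covariate array U; 2-D arrays are matched
#' to the 0+ and >0+ log-abundances and the sampling areas by name
#' patterns (`0/juv/yoy`, `1/ad/old/sup`, `s/area/surf`) with shape
#' consistency checks.
#'
#' @param path file path (`.rds`, `.RData`/`.rda`).
#' @return list with `panel` (an `abundance_panel`), `U`
#'   (`4 x n x T` array), `variables` (discovery report), `n_sites`,
#'   `n_years`.
#' @export
import_supplementary <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("file not found:", path))
  schema_stop <- function(msg, vars) {
    found <- vapply(names(vars), function(nm) {
      d <- dim(vars[[nm]])
      paste0(nm, " [", if (is.null(d)) length(vars[[nm]])
             else paste(d, collapse = "x"), "]")
    }, "")
    stop(errorCondition(
      paste0(msg, "; variables found: ", paste(found, collapse = ", ")),
      class = c("fishdyn_schema_mismatch", "error")))
  }
  vars <- tryCatch({
    if (grepl("\\.rds$", path, ignore.case = TRUE)) {
      obj <- readRDS(path)
      if (!is.list(obj) || is.null(names(obj)))
        stop("RDS content is not a named list")
      obj
    } else {
      e <- new.env()
      load(path, envir = e)
      as.list(e)
    }
  }, error = function(e)
    stop(errorCondition(
      paste("cannot parse", path, ":", conditionMessage(e)),
      class = c("fishdyn_schema_mismatch", "error"))))

  is2d <- vapply(vars, function(v) is.numeric(v) && length(dim(v)) == 2L,
                 TRUE)
  is3d <- vapply(vars, function(v) is.numeric(v) && length(dim(v)) == 3L,
                 TRUE)
  pick <- function(pattern, pool) {
    hits <- pool[grepl(pattern, pool, ignore.case = TRUE)]
    if (length(hits) == 1L) hits else NA_character_
  }
  m2 <- names(vars)[is2d]
  nm_s <- pick("^(s$|area|surf)", m2)
  rest <- setdiff(m2, nm_s)
  nm_x0 <- pick("(^|[^0-9])0|juv|yoy", rest)
  nm_x1 <- pick("1|ad|old|sup", setdiff(rest, nm_x0))
  nm_u <- names(vars)[is3d]
  if (any(is.na(c(nm_s, nm_x0, nm_x1))) || length(nm_u) != 1L)
    schema_stop("could not identify X0/X1/S/U arrays", vars)
  X0 <- vars[[nm_x0]]; X1 <- vars[[nm_x1]]; S <- vars[[nm_s]]
  if (!all(dim(X0) == dim(X1)) || !all(dim(X0) == dim(S)))
    schema_stop("X0/X1/S dimensions disagree", vars)
  U <- vars[[nm_u]]
  jdim <- which(dim(U) == 4L)
  if (!length(jdim)) schema_stop("no covariate extent of 4 in U", vars)
  jdim <- jdim[1L]
  n <- nrow(X0); T <- ncol(X0)
  perm <- c(jdim, setdiff(1:3, jdim))
  U <- aperm(U, perm)
  if (dim(U)[2L] == T && dim(U)[3L] == n) U <- aperm(U, c(1L, 3L, 2L))
  if (dim(U)[2L] != n || dim(U)[3L] != T)
    schema_stop("U extents do not match the abundance arrays", vars)
  mask <- !is.na(X0) & !is.na(X1)
  panel <- abundance_panel(X0, X1, S, mask,
                           sites = rownames(X0) %||% sprintf("S%03d", 1:n),
                           years = colnames(X0) %||% seq_len(T))
  list(panel = panel, U = U,
       variables = list(X0 = nm_x0, X1 = nm_x1, S = nm_s, U = nm_u),
       n_sites = n, n_years = T)
}
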