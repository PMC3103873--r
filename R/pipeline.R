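comparison_methods <- c("censored_likelihood",
                        paste0("substitute_", 0:4), "exclusion")

fit_by_label <- function(label, data, priors, control) {
  if (label == "censored_likelihood")
    cenpois(data, priors, control, method = "censored")
  else if (label == "exclusion")
    cenpois(data, priors, control, method = "exclude")
  else
    cenpois(data, priors, control, method = "substitute",
            sub_value = as.integer(sub("substitute_", "", label)))
}

#' Side-by-side comparison of censoring treatments
#'
#' Fits the censored-likelihood model and the six naive treatments
#' (substitution of 0 through 4, and exclusion) to the same dataset from a
#' shared base seed, and collects the mercury relative risk, its 95%
#' interval, and the convergence verdict of each fit into one table. A fit
#' that fails the R-hat thresholds is flagged but the table is still
#' emitted.
#'
#' @param data A [district_data] object.
#' @param priors A [prior_spec].
#' @param control An [mcmc_control]; its seed is reused by every fit so
#'   method contrasts are not confounded by seed noise.
#' @param methods Character subset of
#'   `c("censored_likelihood", "substitute_0", ..., "substitute_4",
#'   "exclusion")`; all by default.
#' @return A data frame of class `"cenpois_comparison"` with columns
#'   `method`, `rr`, `lower`, `upper`, `rhat_ok`, `max_rhat`, `seed`,
#'   `n_iter` (full precision; the print method rounds to 2 decimals).
#' @export
run_comparison <- function(data, priors = prior_spec(),
                           control = mcmc_control(),
                           methods = comparison_methods) {
  stopifnot(inherits(data, "district_data"))
  if (!length(methods)) stop("at least one method must be requested")
  bad <- setdiff(methods, comparison_methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  rows <- lapply(methods, function(m) {
    fit <- fit_by_label(m, data, priors, control)
    s <- summarize_chains(fit)
    rr <- attr(s, "rr_mercury")
    conv <- check_convergence(fit)
    data.frame(method = m, rr = rr$mean, lower = rr$lower, upper = rr$upper,
               rhat_ok = attr(conv, "pass"), max_rhat = max(conv$rhat),
               seed = control$seed, n_iter = control$n_iter)
  })
  structure(do.call(rbind, rows),
            class = c("cenpois_comparison", "data.frame"))
}

#' @export
print.cenpois_comparison <- function(x, ...) {
  cat("Mercury RR per 1000 lbs, by censored-data treatment\n")
  df <- data.frame(method = x$method,
                   RR = sprintf("%.2f", x$rr),
                   `95% CI` = sprintf("%.2f, %.2f", x$lower, x$upper),
                   converged = ifelse(x$rhat_ok, "yes", "NO"),
                   check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Serialize a comparison table
#'
#' Writes the full-precision table as CSV and/or JSON.
#'
#' @param x A `cenpois_comparison`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_comparison <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "cenpois_comparison"))
  if (!is.null(csv))
    utils::write.csv(as.data.frame(x), csv, row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(x), json, auto_unbox = TRUE,
                         digits = NA)
  invisible(x)
}

#' Prior sensitivity of the mercury relative risk
#'
#' Refits the censored-likelihood model with the mercury coefficient's prior
#' recentered on `log(center_rr)` (variance unchanged) and reports both RR
#' summaries and their absolute difference. A small difference relative to
#' the interval width indicates the prior is not driving the estimate.
#'
#' @param data A [district_data] object.
#' @param center_rr Positive RR on which to center the alternative prior.
#' @param priors Baseline [prior_spec].
#' @param control An [mcmc_control]; both fits share its seed.
#' @return A list of class `"cenpois_sensitivity"`: `default`, `recentered`
#'   (each `list(mean, lower, upper)`), `center_rr` and `abs_diff`.
#' @export
prior_sensitivity <- function(data, center_rr, priors = prior_spec(),
                              control = mcmc_control()) {
  if (center_rr <= 0) stop("center_rr must be positive")
  alt_mean <- priors$beta_mean
  alt_mean[1] <- log(center_rr)
  alt <- prior_spec(mu_mean = priors$mu_mean, mu_var = priors$mu_var,
                    beta_mean = alt_mean, beta_var = priors$beta_var,
                    sigma0_sq_upper = priors$sigma0_sq_upper)
  f0 <- cenpois(data, priors, control, method = "censored")
  f1 <- cenpois(data, alt, control, method = "censored")
  rr0 <- attr(summarize_chains(f0), "rr_mercury")
  rr1 <- attr(summarize_chains(f1), "rr_mercury")
  structure(list(default = rr0, recentered = rr1, center_rr = center_rr,
                 abs_diff = abs(rr0$mean - rr1$mean)),
            class = "cenpois_sensitivity")
}

#' @export
print.cenpois_sensitivity <- function(x, ...) {
  cat(sprintf("Prior sensitivity (mercury prior recentered on log(%.3g)):\n",
              x$center_rr))
  cat(sprintf("  default prior:    RR %.2f (%.2f, %.2f)\n",
              x$default$mean, x$default$lower, x$default$upper))
  cat(sprintf("  recentered prior: RR %.2f (%.2f, %.2f)\n",
              x$recentered$mean, x$recentered$lower, x$recentered$upper))
  cat(sprintf("  |difference in RR|: %.3f\n", x$abs_diff))
  invisible(x)
}

#' Replicated simulation study of censoring treatments
#'
#' Repeatedly generates datasets from a configuration with known truth, fits
#' the requested treatments to each replicate, and aggregates bias, RMSE,
#' empirical 95%-interval coverage (with its binomial Monte Carlo standard
#' error) and median interval width per method, all on the RR scale.
#' Deterministic given `config$seed`: per-replicate data and MCMC seeds are
#' derived from it.
#'
#' @param config A [sim_config]; its `true_params` define the estimand
#'   `RR = exp(beta_mercury)`.
#' @param n_reps Number of replications (at least 2).
#' @param control An [mcmc_control] used for every fit (its `seed` field is
#'   overridden per replicate).
#' @param methods Methods to fit per replicate, as in [run_comparison()].
#' @return An object of class `"simulation_study"`: `summary` (one row per
#'   method: `bias`, `rmse`, `coverage`, `coverage_se`, `median_width`),
#'   `reps` (per-replicate RR and interval), `rr_true` and `n_reps`.
#' @export
simulation_study <- function(config, n_reps, control = mcmc_control(),
                             methods = c("censored_likelihood",
                                         "substitute_0", "substitute_4",
                                         "exclusion")) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 2) stop("n_reps must be at least 2")
  rr_true <- exp(config$true_params$beta[["mercury"]])
  set.seed(config$seed)
  data_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  mcmc_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- data_seeds[r]
    d <- generate_dataset(cfg)$data
    ctl <- control
    ctl$seed <- mcmc_seeds[r]
    rows <- lapply(methods, function(m) {
      fit <- fit_by_label(m, d, prior_spec(), ctl)
      rr <- attr(summarize_chains(fit), "rr_mercury")
      data.frame(rep = r, method = m, rr = rr$mean,
                 lower = rr$lower, upper = rr$upper)
    })
    reps[[r]] <- do.call(rbind, rows)
  }
  reps <- do.call(rbind, reps)

  agg <- do.call(rbind, lapply(methods, function(m) {
    sub <- reps[reps$method == m, ]
    cov <- mean(sub$lower <= rr_true & rr_true <= sub$upper)
    data.frame(method = m,
               bias = mean(sub$rr) - rr_true,
               median_bias = stats::median(sub$rr) - rr_true,
               rmse = sqrt(mean((sub$rr - rr_true)^2)),
               coverage = cov,
               coverage_se = sqrt(cov * (1 - cov) / nrow(sub)),
               median_width = stats::median(sub$upper - sub$lower))
  }))
  structure(list(summary = agg, reps = reps, rr_true = rr_true,
                 n_reps = n_reps, config_digest = config$seed),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d replications, true RR = %.3f\n",
              x$n_reps, x$rr_true))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Prevalence-versus-exposure export
#'
#' A plain data table for plotting observed district prevalence against
#' county exposure together with fitted prevalence curves: the points use a
#' fixed-value substitution (default 3) to place the suppressed districts,
#' and each supplied fit contributes its predicted prevalence over an
#' exposure grid, holding the other covariates at their data means and the
#' county intercept at zero.
#'
#' @param data A [district_data] object.
#' @param fits Named list of [cenpois] fits (names label the curves).
#' @param sub_value Substituted count used to place censored points.
#' @param n_grid Number of exposure grid points for the curves.
#' @return A list with data frames `points` (`mercury`, `prevalence`,
#'   `censored`) and `curves` (`method`, `mercury`, `prevalence`).
#' @export
prevalence_curve_data <- function(data, fits = list(), sub_value = 3,
                                  n_grid = 50) {
  stopifnot(inherits(data, "district_data"))
  shown <- substitute_censored(data, sub_value)
  pts <- data.frame(mercury = shown$mercury,
                    prevalence = shown$count_code / shown$district_size,
                    censored = censoring_status(data) == "interval_censored")
  grid <- seq(0, max(data$mercury), length.out = n_grid)
  curves <- do.call(rbind, lapply(names(fits), function(nm) {
    cf <- coef(fits[[nm]])
    X <- design_matrix(data)
    xm <- colMeans(X)
    lp <- cf[["mu"]] + cf[["mercury"]] * grid +
      sum(cf[beta_names[-1]] * xm[-1])
    data.frame(method = nm, mercury = grid, prevalence = exp(lp))
  }))
  list(points = pts, curves = curves)
}
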