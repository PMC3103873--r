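#' MCMC sampler settings
#'
#' Controls the Metropolis-within-Gibbs run. The documented full-scale
#' default mirrors standard practice for this model class: 100,000 iterations
#' per chain, 3 chains, the first half discarded as burn-in. Proposal scales
#' adapt only during burn-in, so retained draws come from a fixed kernel.
#'
#' @param n_iter Iterations per chain (default 100000).
#' @param n_chains Number of chains (default 3).
#' @param burn_in_fraction Fraction of iterations discarded (default 0.5).
#' @param seed Integer seed; the entire run is deterministic given it.
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#'
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 100000L, n_chains = 3L,
                         burn_in_fraction = 0.5, seed = 1L, thin = 1L) {
  n_iter <- as.integer(n_iter)
  n_chains <- as.integer(n_chains)
  thin <- as.integer(thin)
  if (n_iter < 1L || n_chains < 1L || thin < 1L)
    stop("n_iter, n_chains and thin must be positive integers")
  if (burn_in_fraction <= 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in (0, 1)")
  if (n_iter * (1 - burn_in_fraction) / thin < 100)
    stop("control must retain at least 100 draws per chain")
  structure(list(n_iter = n_iter, n_chains = n_chains,
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed), thin = thin),
            class = "mcmc_control")
}

continuous_covariates <- c("mercury", "pct_white", "taxbase", "pct_econ")

#' Run the MCMC sampler
#'
#' Samples the posterior of the censored hierarchical Poisson model by
#' adaptive random-walk Metropolis-within-Gibbs over blocks: the intercept,
#' each fixed-effect coefficient, each county random intercept, and the
#' random-effect variance (whose proposals outside the uniform prior support
#' are rejected outright). Continuous covariates are centered internally for
#' sampler conditioning and the intercept is mapped back to the original
#' scale in the returned draws, so reported parameters are unaffected.
#'
#' Chain 1 starts at the reference point (`mu` at its prior mean, zero
#' coefficients and county effects, unit variance); later chains start from
#' small deterministic perturbations of it so the between-chain diagnostic
#' sees dispersed starting points.
#'
#' @param x A [district_data] object (may have zero rows, in which case the
#'   prior is the target distribution).
#' @param priors A [prior_spec].
#' @param control An [mcmc_control].
#' @param fixed Optional list pinning parameters during sampling, for
#'   diagnostics and oracle comparisons: `sigma0_sq` (numeric) fixes the
#'   variance; `beta` (length-7 numeric with `NA` for free entries) fixes
#'   individual coefficients.
#'
#' @return An object of class `"chain_set"`: a 3-d array of retained draws
#'   indexed (iteration, parameter, chain), plus acceptance rates and the
#'   county ordering.
#' @export
run_mcmc <- function(x, priors = prior_spec(), control = mcmc_control(),
                     fixed = list()) {
  stopifnot(inherits(x, "district_data"), inherits(priors, "prior_spec"),
            inherits(control, "mcmc_control"))
  scheme <- attr(x, "scheme")
  n <- nrow(x)
  county_ids <- unique(x$county_id)
  J <- length(county_ids)

  X <- if (n > 0) design_matrix(x) else matrix(0, 0, 7)
  xbar <- rep(0, 7)
  if (n > 0) {
    xbar <- colMeans(X)
    X <- sweep(X, 2L, xbar)
  }
  cens <- as.integer(censoring_status(x, scheme) == "interval_censored" &
                       !attr(x, "resolved"))
  ycode <- as.integer(x$count_code)
  ycode[cens == 1L] <- 0L  # ignored by the censored branch
  county_idx <- match(x$county_id, county_ids) - 1L

  # the exposure is county-level: when it is constant within county, the
  # sampler can use a likelihood-invariant translation move against the
  # county intercepts, which otherwise confound it
  county_x <- numeric(0)
  if (n > 0 && J > 0) {
    rng <- tapply(X[, "mercury"], x$county_id, function(v) max(v) - min(v))
    if (all(rng < 1e-12))
      county_x <- X[match(county_ids, x$county_id), "mercury"]
  }

  update_beta <- rep(TRUE, 7)
  beta_init <- rep(0, 7)
  if (!is.null(fixed$beta)) {
    fb <- rep_len(as.numeric(fixed$beta), 7L)
    update_beta <- is.na(fb)
    beta_init[!is.na(fb)] <- fb[!is.na(fb)]
  }
  update_s2 <- is.null(fixed$sigma0_sq)
  s2_init <- if (update_s2) 1 else as.numeric(fixed$sigma0_sq)
  if (s2_init <= 0 || (update_s2 && s2_init >= priors$sigma0_sq_upper))
    stop("initial sigma0_sq outside the prior support")

  burn <- floor(control$n_iter * control$burn_in_fraction)
  n_keep <- (control$n_iter - burn) %/% control$thin
  par_names <- c("mu", beta_names, "sigma0_sq",
                 if (J > 0) paste0("b[", county_ids, "]"))
  draws <- array(NA_real_, dim = c(n_keep, length(par_names), control$n_chains),
                 dimnames = list(NULL, par_names, paste0("chain", seq_len(control$n_chains))))
  accept <- vector("list", control$n_chains)

  set.seed(control$seed)
  for (ch in seq_len(control$n_chains)) {
    theta_init <- c(priors$mu_mean, beta_init)
    s2_ch <- s2_init
    if (ch > 1L) {  # dispersed starts for the convergence diagnostic
      theta_init[1] <- theta_init[1] + stats::rnorm(1, 0, 0.5)
      jit <- stats::rnorm(7, 0, 0.02)
      theta_init[-1][update_beta] <- theta_init[-1][update_beta] + jit[update_beta]
      if (update_s2)
        s2_ch <- min(max(s2_init * exp(stats::rnorm(1, 0, 0.3)), 1e-3),
                     priors$sigma0_sq_upper * 0.9)
    }
    res <- .sampler_cpp(ycode, cens, log(x$district_size), X, county_idx, J,
                        scheme$lower, scheme$upper, xbar,
                        priors$mu_mean, priors$mu_var,
                        priors$beta_mean, priors$beta_var,
                        priors$sigma0_sq_upper,
                        theta_init, rep(0, J), s2_ch,
                        update_beta, update_s2,
                        county_x, length(county_x) > 0,
                        control$n_iter, burn, control$thin)
    draws[, , ch] <- res$draws
    accept[[ch]] <- list(fixed = res$accept_fixed,
                         county = res$accept_county,
                         sigma0_sq = res$accept_sigma0_sq)
  }

  structure(list(draws = draws, parameter_names = par_names,
                 county_ids = county_ids, accept = accept,
                 control = control, priors = priors),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("chain_set: %d chains x %d retained draws x %d parameters\n",
              d[3], d[1], d[2]))
  invisible(x)
}

#' Pooled draws matrix
#'
#' Concatenates the retained draws of all chains into one matrix with one
#' column per parameter.
#'
#' @param x A `chain_set`.
#' @param ... Unused.
#' @return Numeric matrix (total retained draws x parameters).
#' @export
as.matrix.chain_set <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(aperm(x$draws, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  colnames(out) <- x$parameter_names
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between-/within-chain variance diagnostic: with `m` chains of
#' `n` draws, `W` the mean within-chain variance and `B/n` the variance of
#' the chain means, the statistic is
#' `sqrt(((n-1)/n * W + (m+1)/m * B/n) / W)`; values near 1 indicate the
#' chains have mixed over a common distribution.
#'
#' Chains with (numerically) zero total variance are flagged as degenerate:
#' the return value carries attribute `degenerate = TRUE` and equals 1 when
#' the chains agree, or `Inf` when constant chains sit at distinct values.
#'
#' @param x A `chain_set` or a [cenpois] fit.
#' @param parameter Parameter name (e.g. `"mercury"`, `"mu"`, `"sigma0_sq"`).
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(x, parameter) {
  if (inherits(x, "cenpois")) x <- x$chains
  stopifnot(inherits(x, "chain_set"))
  if (!parameter %in% x$parameter_names)
    stop("unknown parameter: ", parameter)
  mat <- x$draws[, parameter, , drop = TRUE]
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  rhat_from_matrix(mat)
}

# columns are chains
rhat_from_matrix <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 10L) stop("at least 10 retained draws per chain are required")
  W <- mean(apply(mat, 2L, stats::var))
  B_over_n <- stats::var(colMeans(mat))
  scale <- mean(abs(mat)) + 1
  if (W < 1e-12 * scale^2) {
    if (B_over_n < 1e-12 * scale^2)
      return(structure(1, degenerate = TRUE))
    return(structure(Inf, degenerate = TRUE))
  }
  vhat <- (n - 1) / n * W + (m + 1) / m * B_over_n
  sqrt(vhat / W)
}

#' Posterior summary of a chain set
#'
#' Per-parameter posterior mean, sd, equal-tailed 95% interval and R-hat from
#' the pooled post-burn-in draws, plus the mercury relative risk summarized
#' on the RR scale: `exp(beta_mercury)` is applied draw by draw before
#' averaging, never to the summaries.
#'
#' @param x A `chain_set` or [cenpois] fit.
#' @return An object of class `"posterior_summary"`: a data frame
#'   (`parameter`, `mean`, `sd`, `lower`, `upper`, `rhat`) with the RR
#'   summary in attribute `rr_mercury` (`mean`, `lower`, `upper`).
#' @export
summarize_chains <- function(x) {
  if (inherits(x, "cenpois")) x <- x$chains
  stopifnot(inherits(x, "chain_set"))
  pooled <- as.matrix(x)
  qs <- apply(pooled, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rhat <- vapply(x$parameter_names, function(p) {
    as.numeric(gelman_rubin(x, p))
  }, numeric(1))
  tab <- data.frame(parameter = x$parameter_names,
                    mean = colMeans(pooled),
                    sd = apply(pooled, 2L, stats::sd),
                    lower = qs[1, ], upper = qs[2, ],
                    rhat = rhat, row.names = NULL)
  rr_draws <- exp(pooled[, "mercury"])
  rr <- list(mean = mean(rr_draws),
             lower = unname(stats::quantile(rr_draws, 0.025)),
             upper = unname(stats::quantile(rr_draws, 0.975)))
  structure(tab, rr_mercury = rr, class = c("posterior_summary", "data.frame"))
}

#' @export
print.posterior_summary <- function(x, n_show = 9L, digits = 3, ...) {
  rr <- attr(x, "rr_mercury")
  cat(sprintf("Mercury RR (per 1000 lbs): %.2f  (95%% CI: %.2f, %.2f)\n\n",
              rr$mean, rr$lower, rr$upper))
  df <- as.data.frame(x)
  print(utils::head(df, n_show), digits = digits, row.names = FALSE)
  if (nrow(df) > n_show)
    cat("... plus", nrow(df) - n_show, "county random intercepts\n")
  invisible(x)
}

#' Convergence check against the dual R-hat thresholds
#'
#' Applies the stricter threshold 1.01 to the mercury coefficient (whose
#' exponential is the reported relative risk) and 1.05 to every other
#' parameter, including county random intercepts.
#'
#' @param x A `chain_set` or [cenpois] fit.
#' @param rr_threshold,other_threshold R-hat thresholds (defaults 1.01, 1.05).
#' @return A data frame of class `"convergence_report"` with columns
#'   `parameter`, `rhat`, `threshold`, `pass`; attribute `pass` holds the
#'   conjunction.
#' @export
check_convergence <- function(x, rr_threshold = 1.01, other_threshold = 1.05) {
  if (inherits(x, "cenpois")) x <- x$chains
  stopifnot(inherits(x, "chain_set"))
  rhat <- vapply(x$parameter_names,
                 function(p) as.numeric(gelman_rubin(x, p)), numeric(1))
  thr <- ifelse(x$parameter_names == "mercury", rr_threshold, other_threshold)
  out <- data.frame(parameter = x$parameter_names, rhat = rhat,
                    threshold = thr, pass = rhat < thr, row.names = NULL)
  structure(out, pass = all(out$pass),
            class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  ok <- attr(x, "pass")
  cat("Convergence:", if (ok) "PASS" else "FAIL", "\n")
  bad <- x[!x$pass, , drop = FALSE]
  if (nrow(bad)) {
    cat("Parameters above threshold:\n")
    print(as.data.frame(bad), row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("max R-hat %.4f (mercury %.4f)\n", max(x$rhat),
                x$rhat[x$parameter == "mercury"]))
  }
  invisible(x)
}

# Batch-means Monte Carlo standard error of a chain mean; accounts for
# autocorrelation without a spectral fit.
mcse_mean <- function(draws) {
  n <- length(draws)
  b <- max(floor(sqrt(n)), 2L)
  nb <- n %/% b
  bm <- colMeans(matrix(draws[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}
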