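#' Prior specification
#'
#' Weakly informative priors for the hierarchical censored Poisson model:
#' a normal prior on the global intercept, independent normal priors on the
#' seven regression coefficients, and a uniform prior on the county
#' random-intercept variance. All normal priors are parameterized by mean and
#' VARIANCE (not precision).
#'
#' @param mu_mean,mu_var Mean and variance of the intercept prior
#'   (defaults -6 and 10).
#' @param beta_mean Length-7 vector of coefficient prior means (default all
#'   zero); order: mercury, pct_white, taxbase, pct_econ, urban, suburban,
#'   other urbanicity. A scalar is recycled.
#' @param beta_var Common coefficient prior variance (default 100).
#' @param sigma0_sq_upper Upper bound of the Uniform(0, upper) prior on the
#'   county random-effect variance (default 50).
#'
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(mu_mean = -6, mu_var = 10, beta_mean = 0,
                       beta_var = 100, sigma0_sq_upper = 50) {
  beta_mean <- rep_len(as.numeric(beta_mean), 7L)
  if (mu_var <= 0 || beta_var <= 0 || sigma0_sq_upper <= 0)
    stop("prior variances and the sigma0^2 upper bound must be positive")
  structure(list(mu_mean = mu_mean, mu_var = mu_var, beta_mean = beta_mean,
                 beta_var = beta_var, sigma0_sq_upper = sigma0_sq_upper),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Priors: mu ~ N(%g, %g); beta_k ~ N(mean, %g); sigma0^2 ~ U(0, %g)\n",
              x$mu_mean, x$mu_var, x$beta_var, x$sigma0_sq_upper))
  if (any(x$beta_mean != 0))
    cat("  beta means:", paste(signif(x$beta_mean, 4), collapse = ", "), "\n")
  invisible(x)
}

beta_names <- c("mercury", "pct_white", "taxbase", "pct_econ",
                "urban", "suburban", "other")

#' Model parameters
#'
#' A full parameter point for the hierarchical model: global intercept `mu`,
#' the seven fixed-effect coefficients `beta` (mercury, pct_white, taxbase,
#' pct_econ and the three urbanicity dummies with rural as reference), the
#' county random-intercept variance `sigma0_sq`, and one random intercept per
#' county.
#'
#' @param mu Global intercept on the log-rate scale.
#' @param beta Numeric vector of length 7 (recycled if scalar).
#' @param sigma0_sq Nonnegative county random-effect variance.
#' @param county_effects Named numeric vector of county intercept deviations
#'   (names are county ids); may be empty.
#'
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(mu, beta = 0, sigma0_sq = 0,
                         county_effects = numeric()) {
  beta <- rep_len(as.numeric(beta), 7L)
  names(beta) <- beta_names
  if (sigma0_sq < 0) stop("sigma0_sq must be nonnegative")
  if (length(county_effects) && is.null(names(county_effects)))
    stop("county_effects must be named by county id")
  structure(list(mu = mu, beta = beta, sigma0_sq = sigma0_sq,
                 county_effects = county_effects),
            class = "model_params")
}

#' Fixed-effect design matrix
#'
#' Expands a district dataset into the covariate matrix of the linear
#' predictor: mercury, pct_white, taxbase, pct_econ and the urbanicity
#' dummies (rural is the reference level and contributes no column).
#'
#' @param x A [district_data] object.
#' @return Numeric matrix with columns `mercury`, `pct_white`, `taxbase`,
#'   `pct_econ`, `urban`, `suburban`, `other`.
#' @keywords internal
design_matrix <- function(x) {
  cbind(mercury = x$mercury,
        pct_white = x$pct_white,
        taxbase = x$taxbase,
        pct_econ = x$pct_econ,
        urban = as.numeric(x$urbanicity == "urban"),
        suburban = as.numeric(x$urbanicity == "suburban"),
        other = as.numeric(x$urbanicity == "other"))
}

#' Linear predictor of the log rate
#'
#' Computes `log(lambda_i) = log(district_size_i) + mu + b_{county(i)} +
#' x_i' beta` for each district. The log enrollment enters as an offset
#' (coefficient fixed at one), so the model describes prevalence rather than
#' raw counts.
#'
#' @param x A [district_data] object.
#' @param params A [model_params] object whose `county_effects` cover every
#'   county in `x`.
#' @return Numeric vector of log rates, one per district.
#' @export
linear_predictor <- function(x, params) {
  stopifnot(inherits(x, "district_data"), inherits(params, "model_params"))
  b <- params$county_effects[x$county_id]
  if (anyNA(b))
    stop("county_effects missing for county id(s): ",
         paste(unique(x$county_id[is.na(b)]), collapse = ", "))
  log(x$district_size) + params$mu + unname(b) +
    drop(design_matrix(x) %*% params$beta)
}

#' Poisson log probability mass
#'
#' @param y Nonnegative integer count(s).
#' @param lam Positive Poisson rate(s).
#' @return `log Pr(Y = y)` evaluated in log space.
#' @export
poisson_logpmf <- function(y, lam) {
  if (any(lam <= 0)) stop("lam must be positive")
  if (any(y < 0 | y != floor(y))) stop("y must be a nonnegative integer")
  stats::dpois(y, lam, log = TRUE)
}

#' Log probability of a censored interval
#'
#' The likelihood contribution of a suppressed count: the log of
#' `Pr(lower < Y <= upper)` under `Y ~ Poisson(lam)`, accumulated by
#' log-sum-exp over the individual mass terms for numerical stability at
#' extreme rates.
#'
#' @param lam Positive Poisson rate(s); vectorized.
#' @param scheme A [censoring_scheme] giving the interval.
#' @return Log interval probability for each rate; always strictly negative.
#' @export
censored_interval_logprob <- function(lam, scheme = censoring_scheme()) {
  if (any(lam <= 0)) stop("lam must be positive")
  ys <- seq.int(scheme$lower + 1L, scheme$upper)
  # rows: interval support points, cols: rates
  lp <- vapply(lam, function(l) stats::dpois(ys, l, log = TRUE),
               numeric(length(ys)))
  lp <- matrix(lp, nrow = length(ys))
  apply(lp, 2L, function(col) {
    m <- max(col)
    m + log(sum(exp(col - m)))
  })
}

#' Censored-data log likelihood
#'
#' Sums the exact Poisson log mass over observed records and the censored
#' interval log probability over sentinel-coded records, each at the
#' district's rate from [linear_predictor()]. Datasets flagged as resolved
#' (censoring removed by substitution) contribute exact terms only.
#'
#' @inheritParams linear_predictor
#' @return Scalar log likelihood.
#' @export
dataset_loglik <- function(x, params) {
  if (nrow(x) == 0L) return(0)
  lp <- linear_predictor(x, params)
  lam <- exp(lp)
  cens <- censoring_status(x) == "interval_censored" & !attr(x, "resolved")
  ll <- 0
  if (any(!cens))
    ll <- ll + sum(poisson_logpmf(x$count_code[!cens], lam[!cens]))
  if (any(cens))
    ll <- ll + sum(censored_interval_logprob(lam[cens], attr(x, "scheme")))
  ll
}

#' Log prior density
#'
#' Normal log densities for the intercept and coefficients, the flat density
#' of the uniform variance prior, and the hierarchical normal terms for the
#' county random intercepts given `sigma0_sq`. A variance outside the uniform
#' support yields `-Inf` (returned, not raised).
#'
#' @param params A [model_params] object.
#' @param priors A [prior_spec] object.
#' @return Scalar log prior density, possibly `-Inf`.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  s2 <- params$sigma0_sq
  if (s2 <= 0 || s2 >= priors$sigma0_sq_upper) return(-Inf)
  lp <- stats::dnorm(params$mu, priors$mu_mean, sqrt(priors$mu_var), log = TRUE) +
    sum(stats::dnorm(params$beta, priors$beta_mean, sqrt(priors$beta_var),
                     log = TRUE)) -
    log(priors$sigma0_sq_upper)
  if (length(params$county_effects))
    lp <- lp + sum(stats::dnorm(params$county_effects, 0, sqrt(s2), log = TRUE))
  lp
}

#' Log posterior density (unnormalized)
#'
#' @inheritParams dataset_loglik
#' @param priors A [prior_spec] object.
#' @return `dataset_loglik(x, params) + log_prior(params, priors)`; `-Inf`
#'   from the prior propagates without evaluating the likelihood.
#' @export
log_posterior <- function(x, params, priors = prior_spec()) {
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + dataset_loglik(x, params)
}
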