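#' Simulation configuration
#'
#' Full description of a synthetic district-level dataset: the county
#' structure, enrollment and exposure distributions, district covariates,
#' the true model parameters, and the censoring scheme. A single latent
#' county "urbanization" score couples the pieces: counties with a high
#' score have more and larger districts, a higher chance of reporting any
#' mercury release, and larger releases. That co-occurrence — small
#' districts concentrated in low-exposure counties — is what induces the
#' negative association between censoring and exposure in released data,
#' without any explicit censoring-given-exposure rule.
#'
#' @param n_counties Number of counties.
#' @param districts_per_county List `mean_extra` (districts beyond the first,
#'   Poisson mean) and `latent_link` (log-linear tilt by the county score).
#' @param size_dist List `meanlog`, `sdlog` (log-normal enrollment),
#'   `latent_link` (shift of `meanlog` per county score unit), `sdlog_link`
#'   (shift of `sdlog` per score unit, floored at 0: urbanized counties
#'   mix very small and very large districts while rural counties are more
#'   homogeneous) and `min` (enrollment floor).
#' @param mercury_dist List `p_zero` (probability a county reports no
#'   release), `shape` and `mean` (gamma distribution of positive releases,
#'   in 1000-lbs units), `max` (reporting cap, 1000 lbs) and `latent_link`
#'   (correlation of release propensity with the county score).
#' @param covariate_dists List with `pct_white = c(mean, sd)`,
#'   `pct_econ = c(mean, sd)` (normal, clamped to `[0, 100]`),
#'   `taxbase = c(meanlog, sdlog)` (log-normal), and `urbanicity =
#'   list(base = <named probs>, latent_link)` tilting urban/suburban odds by
#'   the county score.
#' @param true_params A [model_params] giving the generative truth
#'   (`county_effects` are drawn at generation time from
#'   `N(0, sigma0_sq)`).
#' @param scheme A [censoring_scheme] applied to the latent counts.
#' @param seed Integer seed; generation is deterministic given it.
#'
#' @return An object of class `"sim_config"`.
#' @seealso [texas_like_config()], [generate_dataset()]
#' @export
sim_config <- function(n_counties,
                       districts_per_county = list(mean_extra = 3, latent_link = 0),
                       size_dist = list(meanlog = log(500), sdlog = 1.2,
                                        latent_link = 0, sdlog_link = 0,
                                        min = 25),
                       mercury_dist = list(p_zero = 0.25, shape = 0.7,
                                           mean = 0.3, max = 1.579,
                                           latent_link = 0.8),
                       covariate_dists = list(
                         pct_white = c(mean = 60, sd = 20),
                         pct_econ = c(mean = 50, sd = 18),
                         taxbase = c(meanlog = 0, sdlog = 0.5),
                         urbanicity = list(
                           base = c(rural = 0.55, urban = 0.15,
                                    suburban = 0.2, other = 0.1),
                           latent_link = 0.8)),
                       true_params = model_params(mu = -6.5, beta = 0,
                                                  sigma0_sq = 0.2),
                       scheme = censoring_scheme(),
                       seed = 1L) {
  if (n_counties < 1) stop("need at least one county")
  md <- mercury_dist
  if (md$p_zero < 0 || md$p_zero > 1) stop("p_zero must lie in [0, 1]")
  up <- covariate_dists$urbanicity$base
  if (any(up < 0) || abs(sum(up) - 1) > 1e-8)
    stop("urbanicity base probabilities must be nonnegative and sum to 1")
  if (true_params$sigma0_sq < 0) stop("sigma0_sq must be nonnegative")
  structure(list(n_counties = as.integer(n_counties),
                 districts_per_county = districts_per_county,
                 size_dist = size_dist, mercury_dist = mercury_dist,
                 covariate_dists = covariate_dists,
                 true_params = true_params, scheme = scheme,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d counties, ~%.1f districts/county, seed %d\n",
              x$n_counties, 1 + x$districts_per_county$mean_extra, x$seed))
  cat(sprintf("  true RR (mercury): %.3f, sigma0^2 = %.3f, mu = %.3f\n",
              exp(x$true_params$beta[["mercury"]]), x$true_params$sigma0_sq,
              x$true_params$mu))
  invisible(x)
}

#' Texas-like default configuration
#'
#' A calibrated configuration emulating the released Texas school-district
#' data: about 254 counties and 1029 districts; roughly 44% of districts
#' with an exact zero count and 35% suppressed (counts 1--4); a zero-inflated,
#' right-skewed county air-release distribution with mean near 0.288 and
#' maximum 1.579 (1000-lbs units); and the negative censoring--exposure
#' association that arises because small districts cluster in low-release
#' counties.
#'
#' @param seed Integer seed stored in the config.
#' @param rr_mercury True relative risk per 1000 lbs encoded in the
#'   generative `beta` for mercury (default 1.4).
#' @return A [sim_config].
#' @export
texas_like_config <- function(seed = 1L, rr_mercury = 1.4) {
  sim_config(
    n_counties = 254L,
    districts_per_county = list(mean_extra = 3.05, latent_link = 0.5),
    size_dist = list(meanlog = log(550), sdlog = 1.35, latent_link = 0.2,
                     sdlog_link = 0.7, min = 25),
    mercury_dist = list(p_zero = 0.25, shape = 0.7, mean = 0.30, max = 1.579,
                        latent_link = 0.8),
    covariate_dists = list(
      pct_white = c(mean = 60, sd = 20),
      pct_econ = c(mean = 50, sd = 18),
      taxbase = c(meanlog = 0, sdlog = 0.5),
      urbanicity = list(base = c(rural = 0.55, urban = 0.15, suburban = 0.2,
                                 other = 0.1),
                        latent_link = 0.8)),
    true_params = model_params(
      mu = -6.8,
      beta = c(log(rr_mercury), 0.004, 0.03, -0.003, 0.25, 0.15, 0.05),
      sigma0_sq = 0.2),
    scheme = censoring_scheme(),
    seed = seed)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a censored district dataset with ground truth
#'
#' Draws a complete dataset from a [sim_config]: county latent scores,
#' county-level exposure shared by all districts in the county, district
#' enrollments and covariates, county random intercepts `N(0, sigma0_sq)`,
#' latent Poisson counts at the true parameters, and finally the released
#' codes with counts in the suppressed interval replaced by the sentinel.
#' Generation is deterministic given `config$seed`.
#'
#' @param config A [sim_config].
#' @return A list with components `data` (a [district_data]) and `truth`
#'   (list: `params`, a [model_params] including the drawn county effects;
#'   `counts`, the named vector of uncensored latent counts; `latent`, the
#'   county score vector).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_counties
  dpc <- config$districts_per_county
  sd_ <- config$size_dist
  md <- config$mercury_dist
  cd <- config$covariate_dists
  tp <- config$true_params
  scheme <- config$scheme

  county_id <- sprintf("c%03d", seq_len(J))
  u <- stats::rnorm(J)

  # districts per county, mean preserved under the latent tilt
  lam_d <- dpc$mean_extra * exp(dpc$latent_link * u - dpc$latent_link^2 / 2)
  n_d <- 1L + stats::rpois(J, lam_d)

  # county exposure: structural zeros plus capped gamma, both tied to u
  rho <- md$latent_link
  z <- rho * u + sqrt(1 - rho^2) * stats::rnorm(J)
  emit <- z > stats::qnorm(md$p_zero)
  q <- (stats::pnorm(z) - md$p_zero) / (1 - md$p_zero)
  mercury_cty <- ifelse(emit,
                        pmin(md$max,
                             stats::qgamma(clamp(q, 1e-12, 1 - 1e-12),
                                           shape = md$shape,
                                           rate = md$shape / md$mean)),
                        0)

  b <- stats::rnorm(J, 0, sqrt(tp$sigma0_sq))
  names(b) <- county_id

  cty <- rep.int(seq_len(J), n_d)
  n <- length(cty)
  sdlog_i <- pmax(0, sd_$sdlog + sd_$sdlog_link * u[cty])
  size <- pmax(sd_$min,
               round(stats::rlnorm(n, sd_$meanlog + sd_$latent_link * u[cty],
                                   sdlog_i)))
  pct_white <- clamp(stats::rnorm(n, cd$pct_white[["mean"]],
                                  cd$pct_white[["sd"]]), 0, 100)
  pct_econ <- clamp(stats::rnorm(n, cd$pct_econ[["mean"]],
                                 cd$pct_econ[["sd"]]), 0, 100)
  taxbase <- stats::rlnorm(n, cd$taxbase[["meanlog"]], cd$taxbase[["sdlog"]])
  ub <- cd$urbanicity$base[urbanicity_levels]
  tilt <- exp(cd$urbanicity$latent_link * u[cty])
  w <- cbind(rural = rep(ub[["rural"]], n),
             urban = ub[["urban"]] * tilt,
             suburban = ub[["suburban"]] * tilt,
             other = rep(ub[["other"]], n))
  urbanicity <- apply(w, 1L, function(p) sample(urbanicity_levels, 1L, prob = p))

  df <- data.frame(district_id = sprintf("d%04d", seq_len(n)),
                   county_id = county_id[cty],
                   count_code = 0L,
                   district_size = size,
                   mercury = mercury_cty[cty],
                   pct_white = pct_white,
                   taxbase = taxbase,
                   pct_econ = pct_econ,
                   urbanicity = urbanicity,
                   stringsAsFactors = FALSE)

  params <- model_params(mu = tp$mu, beta = tp$beta,
                         sigma0_sq = tp$sigma0_sq, county_effects = b)
  # latent counts at the truth, then administrative suppression
  shell <- district_data(df, scheme = scheme, resolved = TRUE)
  lam <- exp(linear_predictor(shell, params))
  y <- stats::rpois(n, lam)
  df$count_code <- ifelse(y > scheme$lower & y <= scheme$upper,
                          scheme$sentinel, y)

  list(data = district_data(df, scheme = scheme),
       truth = list(params = params,
                    counts = stats::setNames(y, df$district_id),
                    latent = stats::setNames(u, county_id)))
}

# ---- config serialization (plain key-value YAML) ----

#' Write / read a simulation configuration
#'
#' Round-trips a [sim_config] through a plain YAML key-value file.
#'
#' @param config A [sim_config].
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns the reconstructed [sim_config].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$true_params
  obj <- unclass(config)
  obj$true_params <- list(mu = tp$mu, beta = as.list(tp$beta),
                          sigma0_sq = tp$sigma0_sq)
  obj$scheme <- unclass(config$scheme)
  obj$covariate_dists <- lapply(config$covariate_dists, function(v) {
    if (is.list(v)) list(base = as.list(v$base), latent_link = v$latent_link)
    else as.list(v)
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim_config(
    n_counties = obj$n_counties,
    districts_per_county = obj$districts_per_county,
    size_dist = obj$size_dist,
    mercury_dist = obj$mercury_dist,
    covariate_dists = list(
      pct_white = unlist(obj$covariate_dists$pct_white),
      pct_econ = unlist(obj$covariate_dists$pct_econ),
      taxbase = unlist(obj$covariate_dists$taxbase),
      urbanicity = list(base = unlist(obj$covariate_dists$urbanicity$base),
                        latent_link = obj$covariate_dists$urbanicity$latent_link)),
    true_params = model_params(mu = obj$true_params$mu,
                               beta = unlist(obj$true_params$beta),
                               sigma0_sq = obj$true_params$sigma0_sq),
    scheme = censoring_scheme(obj$scheme$lower, obj$scheme$upper,
                              obj$scheme$sentinel),
    seed = obj$seed)
}
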