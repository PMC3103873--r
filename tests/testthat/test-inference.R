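test_that("mcmc control validates its fields", {
  expect_error(mcmc_control(burn_in_fraction = 1), "burn_in_fraction")
  expect_error(mcmc_control(n_iter = 150), "at least 100 draws")
  expect_silent(mcmc_control(n_iter = 200, seed = 1))
})

test_that("sampling an empty dataset recovers the prior", {
  ch <- run_mcmc(empty_districts(),
                 control = mcmc_control(n_iter = 16000, n_chains = 2, seed = 42))
  pooled <- as.matrix(ch)
  mu <- pooled[, "mu"]
  se_mu <- cenpois:::mcse_mean(mu)
  expect_lt(abs(mean(mu) - (-6)) / se_mu, 3.5)
  se_var <- cenpois:::mcse_mean((mu - mean(mu))^2)
  expect_lt(abs(var(mu) - 10), 3.5 * se_var)
  hg <- pooled[, "mercury"]
  expect_lt(abs(mean(hg)) / cenpois:::mcse_mean(hg), 3.5)
  s2 <- pooled[, "sigma0_sq"]
  expect_true(all(s2 > 0 & s2 < 50))
  expect_lt(abs(mean(s2) - 25), 3 * cenpois:::mcse_mean(s2) + 0.5)
})

test_that("a full run is deterministic given the seed", {
  d <- generate_dataset(small_config(2))$data
  ch1 <- run_mcmc(d, control = fast_control(7, n_iter = 600))
  ch2 <- run_mcmc(d, control = fast_control(7, n_iter = 600))
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- run_mcmc(d, control = fast_control(8, n_iter = 600))
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("gelman-rubin behaves on shared, separated and degenerate chains", {
  set.seed(5)
  n <- 4000
  shared <- fake_chain_set(list(matrix(rnorm(n), ncol = 1),
                                matrix(rnorm(n), ncol = 1),
                                matrix(rnorm(n), ncol = 1)), "mu")
  expect_lt(gelman_rubin(shared, "mu"), 1.02)
  expect_gte(gelman_rubin(shared, "mu"), 1 - 1e-6)

  apart <- fake_chain_set(list(matrix(0, n, 1), matrix(1, n, 1)), "mu")
  r <- gelman_rubin(apart, "mu")
  expect_true(is.infinite(r))
  expect_true(attr(r, "degenerate"))

  same <- matrix(rnorm(n), ncol = 1)
  dup <- fake_chain_set(list(same, same), "mu")
  r2 <- gelman_rubin(dup, "mu")
  expect_true(is.finite(r2))
  expect_lt(r2, 1.001)

  const <- fake_chain_set(list(matrix(2, n, 1), matrix(2, n, 1)), "mu")
  r3 <- gelman_rubin(const, "mu")
  expect_equal(as.numeric(r3), 1)
  expect_true(attr(r3, "degenerate"))

  expect_error(gelman_rubin(shared, "nope"), "unknown parameter")
})

test_that("posterior summaries transform draws, not summaries", {
  set.seed(8)
  n <- 2000
  mk <- function(beta1) {
    cbind(rnorm(n, -6, 0.1), beta1, matrix(rnorm(n * 6, 0, 0.1), n),
          runif(n, 0.1, 0.3))
  }
  nm <- c("mu", "mercury", "pct_white", "taxbase", "pct_econ", "urban",
          "suburban", "other", "sigma0_sq")
  # all mercury draws zero: RR exactly 1 with a degenerate interval
  cs0 <- fake_chain_set(list(mk(rep(0, n)), mk(rep(0, n))), nm)
  rr0 <- attr(summarize_chains(cs0), "rr_mercury")
  expect_equal(rr0$mean, 1)
  expect_equal(c(rr0$lower, rr0$upper), c(1, 1))

  # near-degenerate draws at log 2: RR mean ~ 2 (lognormal mean, small var)
  b <- rnorm(2 * n, log(2), 1e-4)
  cs2 <- fake_chain_set(list(mk(b[1:n]), mk(b[(n + 1):(2 * n)])), nm)
  rr2 <- attr(summarize_chains(cs2), "rr_mercury")
  expect_equal(rr2$mean, 2, tolerance = 1e-3)

  # interval endpoints are the exp-transformed quantiles of beta1
  b3 <- rnorm(n, 0.3, 0.2)
  cs3 <- fake_chain_set(list(mk(b3), mk(b3)), nm)
  rr3 <- attr(summarize_chains(cs3), "rr_mercury")
  pooled_b <- c(b3, b3)
  expect_equal(rr3$lower, exp(unname(quantile(pooled_b, 0.025))),
               tolerance = 1e-5)
  expect_equal(rr3$upper, exp(unname(quantile(pooled_b, 0.975))),
               tolerance = 1e-5)
  expect_lte(rr3$lower, rr3$upper)
})

test_that("convergence check applies 1.01 to mercury and 1.05 elsewhere", {
  set.seed(13)
  n <- 1000
  # two chains offset enough for an R-hat between the two thresholds
  offset_draws <- function() list(matrix(rnorm(n), ncol = 1),
                                  matrix(rnorm(n) + 0.3, ncol = 1))
  d1 <- offset_draws()
  nm <- c("mu", "mercury", "pct_white", "taxbase", "pct_econ", "urban",
          "suburban", "other", "sigma0_sq")
  mats <- lapply(1:2, function(ch) {
    cols <- lapply(nm, function(p) if (p %in% c("mercury", "taxbase"))
      d1[[ch]] else matrix(rnorm(n), ncol = 1))
    do.call(cbind, cols)
  })
  cs <- fake_chain_set(mats, nm)
  r <- gelman_rubin(cs, "mercury")
  expect_gt(r, 1.01)  # guard: the engineered offset lands between thresholds
  expect_lt(r, 1.05)
  rep_ <- check_convergence(cs)
  expect_false(rep_$pass[rep_$parameter == "mercury"])
  expect_true(rep_$pass[rep_$parameter == "taxbase"])  # same draws, looser bar
  expect_false(attr(rep_, "pass"))

  ok <- fake_chain_set(list(mats[[1]], mats[[1]] + rnorm(n * 9, 0, 1e-8)), nm)
  # identical-distribution chains pass everything
  set.seed(14)
  mats_ok <- lapply(1:2, function(ch) matrix(rnorm(n * 9), n, 9))
  expect_true(attr(check_convergence(fake_chain_set(mats_ok, nm)), "pass"))
})

test_that("fit object methods are coherent", {
  d <- generate_dataset(small_config(6))$data
  fit <- cenpois(d, control = fast_control(3, n_iter = 1200))
  cf <- coef(fit)
  expect_named(cf, c("mu", "mercury", "pct_white", "taxbase", "pct_econ",
                     "urban", "suburban", "other"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= ci[, 2]))
  lam <- fitted(fit)
  expect_equal(lam, predict(fit, type = "rate") * d$district_size)
  expect_equal(log(lam), predict(fit, type = "link"))
  r <- residuals(fit)
  cens <- censoring_status(d) == "interval_censored"
  expect_true(all(is.na(r[cens])))
  expect_true(all(is.finite(r[!cens])))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "district_data")
  expect_equal(nrow(sims[[1]]), nrow(d))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("Mercury RR", out)))
})
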