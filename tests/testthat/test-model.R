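test_that("linear predictor matches its closed form and offset property", {
  d <- make_districts(c(0L), size = 1000)
  p0 <- model_params(mu = -6, county_effects = c(c1 = 0))
  lp <- linear_predictor(d, p0)
  expect_equal(lp, log(1000) - 6)
  expect_equal(exp(lp), 1000 * exp(-6), tolerance = 1e-12)  # lambda ~ 2.4788

  # zero mercury coefficient: predictor invariant to exposure
  d_hg <- make_districts(c(0L), size = 1000, mercury = 7.3)
  expect_equal(linear_predictor(d_hg, p0), lp)

  # doubling enrollment adds log 2
  d2 <- make_districts(c(0L), size = 2000)
  expect_equal(linear_predictor(d2, p0), lp + log(2))

  # urbanicity dummies: rural is reference, each level adds its coefficient
  pb <- model_params(mu = -6, beta = c(0, 0, 0, 0, 0.5, 0.3, 0.1),
                     county_effects = c(c1 = 0))
  for (lev in c("rural", "urban", "suburban", "other")) {
    dl <- make_districts(c(0L), size = 1000, urbanicity = lev)
    shift <- switch(lev, rural = 0, urban = 0.5, suburban = 0.3, other = 0.1)
    expect_equal(linear_predictor(dl, pb), lp + shift)
  }

  expect_error(linear_predictor(d, model_params(mu = -6)), "county_effects")
})

test_that("poisson log-pmf agrees with direct arithmetic", {
  expect_equal(poisson_logpmf(0, 1), -1)
  expect_equal(poisson_logpmf(1, 1), -1)
  expect_equal(poisson_logpmf(4, 2.5), log(exp(-2.5) * 2.5^4 / 24))
  expect_error(poisson_logpmf(1, 0), "positive")
  expect_error(poisson_logpmf(-1, 1), "nonnegative")
})

test_that("censored interval log-probability matches direct summation", {
  # lambda = 1, interval (0,4]: e^-1 (1 + 1/2 + 1/6 + 1/24)
  expect_equal(censored_interval_logprob(1),
               log(exp(-1) * (1 + 1/2 + 1/6 + 1/24)))
  expect_error(censored_interval_logprob(0), "positive")
  # always a strictly negative log-probability, vanishing at both extremes
  expect_true(all(censored_interval_logprob(c(1e-8, 0.1, 1, 10, 100)) < 0))
  expect_lt(censored_interval_logprob(1e-8), -15)
  expect_lt(censored_interval_logprob(100), -50)
})

test_that("interval probability agrees with the CDF oracle and normalizes", {
  lam <- exp(seq(log(0.001), log(50), length.out = 200))
  ours <- censored_interval_logprob(lam)
  oracle <- log(stats::ppois(4, lam) - stats::ppois(0, lam))
  expect_lt(max(abs(ours - oracle)), 1e-10)
  total <- stats::dpois(0, lam) + exp(ours) +
    stats::ppois(4, lam, lower.tail = FALSE)
  expect_lt(max(abs(total - 1)), 1e-12)
})

test_that("interval probability is unimodal in lambda with interior maximum", {
  lam <- exp(seq(log(0.001), log(50), length.out = 400))
  v <- censored_interval_logprob(lam)
  k <- which.max(v)
  expect_gt(k, 1)
  expect_lt(k, length(lam))
  expect_true(all(diff(v[seq_len(k)]) > 0))
  expect_true(all(diff(v[k:length(v)]) < 0))
})

test_that("dataset log likelihood decomposes over records", {
  d1 <- make_districts(c(3L), size = 1200, resolved = TRUE)
  p <- model_params(mu = -6, county_effects = c(c1 = 0.2))
  lam <- exp(log(1200) - 6 + 0.2)
  expect_equal(dataset_loglik(d1, p), poisson_logpmf(3, lam))

  d <- make_districts(c(0L, -999L, 6L), county = c("c1", "c1", "c2"),
                      size = c(500, 900, 4000))
  p2 <- model_params(mu = -6, beta = c(0.3, 0.001, 0, 0, 0, 0, 0),
                     county_effects = c(c1 = 0.1, c2 = -0.2))
  lp <- linear_predictor(d, p2)
  manual <- poisson_logpmf(0, exp(lp[1])) +
    censored_interval_logprob(exp(lp[2])) +
    poisson_logpmf(6, exp(lp[3]))
  expect_equal(dataset_loglik(d, p2), manual)
  expect_equal(dataset_loglik(empty_districts(), p2), 0)
})

test_that("censored likelihood equals the brute-force enumeration oracle", {
  # enumerate every completion y in {1..4}^k of the censored records and
  # log-sum-exp the joint likelihoods
  d <- make_districts(c(-999L, 7L, -999L, 0L, -999L),
                      county = c("c1", "c1", "c2", "c2", "c2"),
                      size = c(700, 2500, 400, 300, 1500))
  p <- model_params(mu = -6.2, beta = c(0.2, 0, 0.01, 0, 0, 0, 0),
                    county_effects = c(c1 = 0.3, c2 = -0.1))
  lam <- exp(linear_predictor(d, p))
  cens_idx <- which(censoring_status(d) == "interval_censored")
  grid <- expand.grid(rep(list(1:4), length(cens_idx)))
  joint <- apply(grid, 1L, function(fill) {
    y <- d$count_code
    y[cens_idx] <- as.integer(fill)
    sum(stats::dpois(y, lam, log = TRUE))
  })
  m <- max(joint)
  oracle <- m + log(sum(exp(joint - m)))
  expect_equal(dataset_loglik(d, p), oracle, tolerance = 1e-12)
})

test_that("log prior matches closed forms and respects the uniform support", {
  pr <- prior_spec()
  p <- model_params(mu = -6, beta = 0, sigma0_sq = 25)
  expected <- -0.5 * log(2 * pi * 10) + 7 * (-0.5 * log(2 * pi * 100)) +
    log(1 / 50)
  expect_equal(log_prior(p, pr), expected)
  expect_identical(log_prior(model_params(mu = -6, sigma0_sq = 60), pr), -Inf)
  expect_identical(log_prior(model_params(mu = -6, sigma0_sq = 0), pr), -Inf)
  # adding one county at the mode contributes -0.5 log(2 pi sigma0^2)
  p1 <- model_params(mu = -6, beta = 0, sigma0_sq = 25,
                     county_effects = c(c1 = 0))
  expect_equal(log_prior(p1, pr) - log_prior(p, pr), -0.5 * log(2 * pi * 25))
})

test_that("log posterior composes likelihood and prior", {
  pr <- prior_spec()
  d <- make_districts(c(0L, -999L), size = c(400, 900))
  p <- model_params(mu = -6, beta = 0.01, sigma0_sq = 2,
                    county_effects = c(c1 = 0.1))
  expect_equal(log_posterior(d, p, pr), dataset_loglik(d, p) + log_prior(p, pr))
  expect_equal(log_posterior(empty_districts(), p, pr), log_prior(p, pr))
  bad <- model_params(mu = -6, sigma0_sq = 60, county_effects = c(c1 = 0))
  expect_identical(log_posterior(d, bad, pr), -Inf)
})
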