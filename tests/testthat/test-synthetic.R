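test_that("generation is deterministic given the seed", {
  cfg <- small_config(11)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$data, g2$data)
  expect_identical(g1$truth$counts, g2$truth$counts)
  g3 <- generate_dataset(small_config(12))
  expect_false(identical(as.data.frame(g1$data), as.data.frame(g3$data)))
  # byte-identical on disk
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_districts(g1$data, p1)
  write_districts(g2$data, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("suppression is a deterministic function of the latent count", {
  g <- generate_dataset(small_config(3))
  scheme <- attr(g$data, "scheme")
  y <- g$truth$counts[g$data$district_id]
  recoded <- ifelse(y > scheme$lower & y <= scheme$upper, scheme$sentinel, y)
  expect_identical(as.integer(recoded), g$data$count_code)
  # no latent 0 or >=5 is ever sentinel-coded
  cens <- g$data$count_code == scheme$sentinel
  expect_true(all(y[cens] >= 1 & y[cens] <= 4))
  expect_true(all(y[!cens] == 0 | y[!cens] > 4))
})

test_that("null configuration reproduces the closed-form Poisson mean", {
  # beta = 0, mu = -6, sigma0 = 0, enrollment fixed at 1000:
  # E[Y] = 1000 exp(-6) ~ 2.4788
  cfg <- sim_config(
    n_counties = 150L,
    districts_per_county = list(mean_extra = 6, latent_link = 0),
    size_dist = list(meanlog = log(1000), sdlog = 0, latent_link = 0,
                     sdlog_link = 0, min = 1000),
    true_params = model_params(mu = -6, beta = 0, sigma0_sq = 0),
    seed = 21)
  g <- generate_dataset(cfg)
  ybar <- mean(g$truth$counts)
  n <- length(g$truth$counts)
  se <- sqrt(1000 * exp(-6) / n)
  expect_lt(abs(ybar - 1000 * exp(-6)), 4 * se)
  expect_true(all(g$data$district_size == 1000))
})

test_that("with no county structure the counts carry no county signal", {
  # sigma0 = 0, beta = 0 and all latent links off: latent counts are
  # exchangeable across counties, so a rank test of counts on county labels
  # rejects at roughly its nominal rate
  pvals <- vapply(1:15, function(s) {
    cfg <- sim_config(
      n_counties = 30L,
      districts_per_county = list(mean_extra = 5, latent_link = 0),
      size_dist = list(meanlog = log(800), sdlog = 0.5, latent_link = 0,
                       sdlog_link = 0, min = 25),
      true_params = model_params(mu = -6, beta = 0, sigma0_sq = 0),
      seed = 1000 + s)
    g <- generate_dataset(cfg)
    y <- g$truth$counts[g$data$district_id]
    stats::kruskal.test(y, factor(g$data$county_id))$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.35)
  expect_gt(mean(pvals), 0.2)
})

test_that("texas-like datasets match the released data's structure", {
  stats <- vapply(1:8, function(s) {
    g <- generate_dataset(texas_like_config(s))
    d <- g$data
    sm <- summarize_counts(d)
    cens <- as.numeric(censoring_status(d) == "interval_censored")
    cty <- !duplicated(d$county_id)
    c(n = sm$total, zero = sm$zero_fraction, cens = sm$censored_fraction,
      rho = suppressWarnings(
        stats::cor(cens, d$mercury, method = "spearman")),
      hg_mean = mean(d$mercury[cty][d$mercury[cty] > 0]),
      hg_max = max(d$mercury))
  }, numeric(6))
  m <- rowMeans(stats)
  expect_gt(m["n"], 950)
  expect_lt(m["n"], 1110)
  expect_lt(abs(m["zero"] - 451 / 1029), 0.05)
  expect_lt(abs(m["cens"] - 362 / 1029), 0.05)
  # censoring is negatively associated with exposure
  expect_lt(m["rho"], 0)
  expect_true(all(stats["rho", ] < 0))
  # emitting-county mean release on the order of 0.288 (1000 lbs), capped
  expect_lt(abs(m["hg_mean"] - 0.288), 0.1)
  expect_lte(m["hg_max"], 1.579)
})

test_that("configs round-trip through YAML", {
  cfg <- texas_like_config(99, rr_mercury = 1.25)
  path <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$true_params$beta, cfg$true_params$beta)
  expect_equal(cfg2$size_dist, cfg$size_dist)
  expect_identical(generate_dataset(cfg2)$data, generate_dataset(cfg)$data)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_counties = 0), "at least one county")
  expect_error(sim_config(n_counties = 5,
                          mercury_dist = list(p_zero = 1.2, shape = 1,
                                              mean = 0.3, max = 1,
                                              latent_link = 0)),
               "p_zero")
})
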