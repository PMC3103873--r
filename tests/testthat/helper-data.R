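# Builders for small in-memory fixtures used across the suite.

make_districts <- function(counts, county = NULL, size = 1000, mercury = 0,
                           pct_white = 50, taxbase = 1, pct_econ = 40,
                           urbanicity = "rural", scheme = censoring_scheme(),
                           resolved = FALSE) {
  n <- length(counts)
  if (is.null(county)) county <- rep("c1", n)
  district_data(data.frame(
    district_id = sprintf("d%03d", seq_len(n)),
    county_id = county,
    count_code = as.integer(counts),
    district_size = rep_len(size, n),
    mercury = rep_len(mercury, n),
    pct_white = rep_len(pct_white, n),
    taxbase = rep_len(taxbase, n),
    pct_econ = rep_len(pct_econ, n),
    urbanicity = rep_len(urbanicity, n),
    stringsAsFactors = FALSE), scheme = scheme, resolved = resolved)
}

empty_districts <- function() {
  district_data(data.frame(
    district_id = character(), county_id = character(),
    count_code = integer(), district_size = numeric(),
    mercury = numeric(), pct_white = numeric(), taxbase = numeric(),
    pct_econ = numeric(), urbanicity = character(),
    stringsAsFactors = FALSE))
}

# The released count distribution for the 2000-2001 Texas school districts,
# expanded to one record per district. Counts above 10 are only released in
# bands; any representative value inside each band gives the same tallies.
table1_marginals <- function() {
  counts <- c(rep(0L, 451), rep(-999L, 362), rep(5L, 18), rep(6L, 16),
              rep(7L, 16), rep(8L, 15), rep(9L, 7), rep(10L, 10),
              rep(15L, 53), rep(30L, 44), rep(60L, 37))
  make_districts(counts,
                 county = paste0("c", rep_len(1:50, length(counts))),
                 size = 5000)
}

# chain_set with externally supplied draws, for diagnostic unit tests
fake_chain_set <- function(draw_list, parameter_names) {
  n <- nrow(draw_list[[1]])
  arr <- array(NA_real_, dim = c(n, length(parameter_names), length(draw_list)),
               dimnames = list(NULL, parameter_names, NULL))
  for (ch in seq_along(draw_list)) arr[, , ch] <- draw_list[[ch]]
  structure(list(draws = arr, parameter_names = parameter_names,
                 county_ids = character(), accept = list(),
                 control = NULL, priors = prior_spec()),
            class = "chain_set")
}

# small fast config for fit-based tests
small_config <- function(seed = 1, rr_mercury = 1.4) {
  cfg <- texas_like_config(seed, rr_mercury)
  cfg$n_counties <- 40L
  cfg
}

fast_control <- function(seed = 1, n_iter = 1500, n_chains = 2) {
  mcmc_control(n_iter = n_iter, n_chains = n_chains, seed = seed)
}
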