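#' Naive censored-data treatment
#'
#' Describes one of the ad hoc treatments of suppressed counts: substituting
#' a fixed value `c` from the closed interval `[0, upper]`, or excluding the
#' suppressed records altogether.
#'
#' @param kind `"substitute"` or `"exclude"`.
#' @param c Fixed substituted count; required for `"substitute"`.
#' @return An object of class `"naive_method"`.
#' @export
naive_method <- function(kind = c("substitute", "exclude"), c = NULL) {
  kind <- match.arg(kind)
  if (kind == "substitute") {
    if (is.null(c)) stop("substitution requires a fixed value c")
    c <- as.integer(c)
  } else {
    c <- NULL
  }
  structure(list(kind = kind, c = c), class = "naive_method")
}

#' Substitute a fixed value for suppressed counts
#'
#' Replaces every sentinel-coded count by the fixed value `c` and flags the
#' result as resolved, so downstream fits treat all counts as exactly
#' observed. Uncensored records are untouched. The returned dataset carries a
#' provenance label so reports always state which transformation produced it.
#'
#' @param x A [district_data] object.
#' @param c Integer in `0:upper` of the scheme.
#' @return A resolved [district_data] object.
#' @export
substitute_censored <- function(x, c) {
  stopifnot(inherits(x, "district_data"))
  scheme <- attr(x, "scheme")
  c <- as.integer(c)
  if (is.na(c) || c < 0L || c > scheme$upper)
    stop("substituted value must lie in [0, ", scheme$upper, "]")
  df <- as.data.frame(x)
  df$count_code[df$count_code == scheme$sentinel] <- c
  district_data(df, scheme = scheme, resolved = TRUE,
                provenance = sprintf("substitute c=%d", c))
}

#' Drop suppressed records
#'
#' Removes every sentinel-coded record, preserving the order of the
#' survivors, and flags the result as resolved.
#'
#' @param x A [district_data] object.
#' @return A resolved [district_data] object with only exact records.
#' @export
exclude_censored <- function(x) {
  stopifnot(inherits(x, "district_data"))
  scheme <- attr(x, "scheme")
  df <- as.data.frame(x)[x$count_code != scheme$sentinel, , drop = FALSE]
  rownames(df) <- NULL
  district_data(df, scheme = scheme, resolved = TRUE, provenance = "exclusion")
}

#' Fit a naive comparator
#'
#' Applies the naive treatment to the data and fits the same hierarchical
#' Poisson model with every count treated as exact, using the same Bayesian
#' machinery as the censored-likelihood fit so that any difference between
#' results is attributable to the censoring treatment alone.
#'
#' @param x A [district_data] object.
#' @param method A [naive_method].
#' @inheritParams cenpois
#' @return A [cenpois] fit.
#' @export
fit_naive <- function(x, method, priors = prior_spec(),
                      control = mcmc_control()) {
  stopifnot(inherits(method, "naive_method"))
  if (method$kind == "substitute")
    cenpois(x, priors, control, method = "substitute", sub_value = method$c)
  else
    cenpois(x, priors, control, method = "exclude")
}
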