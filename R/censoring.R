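#' Administrative censoring scheme
#'
#' Describes how a data-releasing agency suppresses small counts: every count
#' strictly inside `(lower, upper]` is replaced in released files by a
#' negative sentinel code, while zeros and counts above `upper` are released
#' exactly. The default scheme matches the common practice of suppressing
#' counts of 1--4 with the code `-999`.
#'
#' @param lower Exclusive lower bound of the suppressed interval (default 0).
#' @param upper Inclusive upper bound of the suppressed interval (default 4).
#' @param sentinel Negative integer code stored in place of suppressed counts
#'   (default `-999`).
#'
#' @return An object of class `"censoring_scheme"`.
#' @examples
#' censoring_scheme()
#' censoring_scheme(upper = 9, sentinel = -99)
#' @export
censoring_scheme <- function(lower = 0L, upper = 4L, sentinel = -999L) {
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  sentinel <- as.integer(sentinel)
  if (lower >= upper)
    stop("censoring scheme requires lower < upper, got (", lower, ", ", upper, "]")
  if (sentinel >= 0L)
    stop("sentinel must be negative so it can never collide with a count")
  structure(list(lower = lower, upper = upper, sentinel = sentinel),
            class = "censoring_scheme")
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("Censoring scheme: counts in (%d, %d] suppressed, sentinel %d\n",
              x$lower, x$upper, x$sentinel))
  invisible(x)
}

is_censoring_scheme <- function(x) inherits(x, "censoring_scheme")

#' Censoring status of observed count codes
#'
#' Maps the released `count_code` column to its observation status: the
#' sentinel code means the count is only known to lie in the suppressed
#' interval; any other code is an exactly observed count.
#'
#' @param x A [district_data] object, or an integer vector of count codes.
#' @param scheme A [censoring_scheme]; defaults to the scheme attached to `x`.
#'
#' @return A factor with levels `"exact"` and `"interval_censored"`, one per
#'   record.
#' @examples
#' censoring_status(c(0L, -999L, 7L), censoring_scheme())
#' @export
censoring_status <- function(x, scheme = attr(x, "scheme")) {
  codes <- if (is.data.frame(x)) x$count_code else x
  if (!is_censoring_scheme(scheme)) stop("a censoring_scheme is required")
  factor(ifelse(codes == scheme$sentinel, "interval_censored", "exact"),
         levels = c("exact", "interval_censored"))
}

district_columns <- c("district_id", "county_id", "count_code", "district_size",
                      "mercury", "pct_white", "taxbase", "pct_econ", "urbanicity")

urbanicity_levels <- c("rural", "urban", "suburban", "other")

#' District-level censored count data
#'
#' Validates a data frame of district records against the nine-column schema
#' used throughout the package and attaches the censoring scheme. A valid
#' `count_code` is either the scheme's sentinel, zero, or an exact count above
#' the suppressed interval; exact counts inside the interval would contradict
#' the suppression rule and are rejected unless the data are flagged as
#' `resolved` (i.e. censoring has been removed by a substitution method, so
#' any nonnegative count is legal).
#'
#' @param df Data frame with columns `district_id`, `county_id`, `count_code`,
#'   `district_size`, `mercury`, `pct_white`, `taxbase`, `pct_econ`,
#'   `urbanicity`.
#' @param scheme A [censoring_scheme].
#' @param resolved Logical; `TRUE` marks a dataset whose censored codes have
#'   been replaced by fixed values, relaxing the suppressed-interval check.
#' @param provenance Character label recording the transformation that
#'   produced the dataset (e.g. `"substitute c=3"`); `NA` for source data.
#'
#' @return A data frame of class `"district_data"` with attributes `scheme`,
#'   `resolved` and `provenance`.
#' @seealso [read_districts()], [write_districts()], [summarize_counts()]
#' @export
district_data <- function(df, scheme = censoring_scheme(), resolved = FALSE,
                          provenance = NA_character_) {
  if (!is.data.frame(df)) stop("df must be a data frame")
  missing_cols <- setdiff(district_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[district_columns]
  df$district_id <- as.character(df$district_id)
  df$county_id <- as.character(df$county_id)
  df$urbanicity <- as.character(df$urbanicity)

  problems <- character()
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(utils::head(idx, 5), collapse = ", "),
                                      if (length(idx) > 5) ", ..." else "", ")"))
  }
  bad(is.na(df$count_code) | df$count_code != as.integer(df$count_code),
      "non-integer count_code")
  bad(is.na(df$district_size) | df$district_size < 1, "district_size < 1")
  bad(is.na(df$mercury) | df$mercury < 0, "negative mercury")
  bad(!df$urbanicity %in% urbanicity_levels,
      paste0("urbanicity not in {", paste(urbanicity_levels, collapse = ", "), "}"))
  bad(duplicated(df$district_id), "duplicated district_id")
  if (!resolved) {
    inside <- df$count_code > scheme$lower & df$count_code <= scheme$upper
    neg <- df$count_code < 0 & df$count_code != scheme$sentinel
    bad(!is.na(df$count_code) & (inside | neg),
        "count_code inside the suppressed interval or an unknown negative code")
  } else {
    bad(!is.na(df$count_code) & df$count_code < 0 &
          df$count_code != scheme$sentinel,
        "negative count_code other than the sentinel")
  }
  if (length(problems))
    stop("invalid district data: ", paste(problems, collapse = "; "))

  df$count_code <- as.integer(df$count_code)
  df$district_size <- as.numeric(df$district_size)
  structure(df, scheme = scheme, resolved = isTRUE(resolved),
            provenance = provenance,
            class = c("district_data", "data.frame"))
}

#' @export
print.district_data <- function(x, ...) {
  s <- summarize_counts(x)
  cat(sprintf("District data: %d districts, %d counties\n",
              nrow(x), length(unique(x$county_id))))
  cat(sprintf("  counts: %d zero, %d censored, %d exact positive\n",
              s$zeros, s$censored, s$exact_positive))
  prov <- attr(x, "provenance")
  if (!is.na(prov)) cat("  provenance:", prov, "\n")
  NextMethod()
}

#' @export
as.data.frame.district_data <- function(x, ...) {
  as.data.frame(unclass(x)[district_columns], stringsAsFactors = FALSE)
}

#' Read district records from CSV
#'
#' Reads the nine-column district CSV (comma-separated, header required,
#' UTF-8), leaving sentinel codes untouched, and validates it against the
#' scheme.
#'
#' @param path Path to a CSV file.
#' @inheritParams district_data
#' @return A validated [district_data] object.
#' @export
read_districts <- function(path, scheme = censoring_scheme(), resolved = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  district_data(df, scheme = scheme, resolved = resolved)
}

#' Write district records to CSV
#'
#' Writes the stable nine-column order with the sentinel preserved literally,
#' so that `read_districts(write_districts(x, p))` reproduces `x`
#' field-for-field.
#'
#' @param x A [district_data] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_districts <- function(x, path) {
  stopifnot(inherits(x, "district_data"))
  utils::write.csv(as.data.frame(x)[district_columns], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Tally exact, zero and censored counts
#'
#' Partitions the records of a dataset into zero counts, interval-censored
#' counts, and exact positive counts (necessarily above the suppressed
#' interval), the three classes released by the agency.
#'
#' @param x A [district_data] object.
#' @return A list with components `zeros`, `censored`, `exact_positive`,
#'   `total`, and the derived `censored_fraction` and `zero_fraction`
#'   (both `NaN` for an empty dataset).
#' @examples
#' d <- district_data(data.frame(
#'   district_id = c("a", "b", "c"), county_id = "1",
#'   count_code = c(0L, -999L, 12L), district_size = 1000,
#'   mercury = 0, pct_white = 50, taxbase = 1, pct_econ = 40,
#'   urbanicity = "rural"))
#' summarize_counts(d)
#' @export
summarize_counts <- function(x) {
  stopifnot(inherits(x, "district_data"))
  scheme <- attr(x, "scheme")
  status <- censoring_status(x, scheme)
  censored <- sum(status == "interval_censored")
  zeros <- sum(status == "exact" & x$count_code == 0L)
  exact_positive <- sum(status == "exact" & x$count_code > 0L)
  total <- nrow(x)
  list(zeros = zeros, censored = censored, exact_positive = exact_positive,
       total = total,
       zero_fraction = zeros / total,
       censored_fraction = censored / total)
}
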