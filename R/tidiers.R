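#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn summarize_sizes `tidy()` returns the binned histogram.
#' @param x a `size_summary`.
#' @param ... unused.
#' @method tidy size_summary
#' @export
tidy.size_summary <- function(x, ...) x$histogram

#' @describeIn summarize_sizes `glance()` returns a one-row tibble with
#'   `n`, `mean_nm`, `sd_nm`, `cv_percent`.
#' @method glance size_summary
#' @export
glance.size_summary <- function(x, ...) {
  tibble::tibble(n = x$n, mean_nm = x$mean, sd_nm = x$sd,
                 cv_percent = x$cv_percent)
}

#' @describeIn sec_trend_fit `tidy()` returns the coefficient table.
#' @param x a `sec_trend`.
#' @param ... unused.
#' @method tidy sec_trend
#' @export
tidy.sec_trend <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = co[, 1], std_error = co[, 2])
}

#' @describeIn sec_trend_fit `glance()` returns `slope`, `intercept`,
#'   `r_squared` and `n` in one row.
#' @method glance sec_trend
#' @export
glance.sec_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' @describeIn aggregate_census `tidy()` returns the census as a tibble
#'   of category and event count.
#' @param x an `aggregate_census`.
#' @param ... unused.
#' @method tidy aggregate_census
#' @export
tidy.aggregate_census <- function(x, ...) {
  tibble::tibble(category = factor(names(x$counts),
                                   levels = c("1", "2", "3", ">=4")),
                 n_events = as.integer(x$counts))
}

#' @describeIn chi_square_census `glance()` returns `statistic`, `df`,
#'   `p_value` in one row.
#' @param x a `census_chisq`.
#' @param ... unused.
#' @method glance census_chisq
#' @export
glance.census_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @describeIn bland_altman `tidy()` returns the per-pair (mean,
#'   difference) points.
#' @param x a `bland_altman`.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$points

#' @describeIn bland_altman `glance()` returns bias, limits of agreement
#'   and the SD of differences.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, lower = x$lower, upper = x$upper,
                 sd_diff = x$sd_diff, n = nrow(x$points))
}

#' @describeIn match_instances `tidy()` returns the matched pairs.
#' @param x a `match_result`.
#' @param ... unused.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @describeIn evaluate_segmentation `glance()` returns the one-row
#'   metric table.
#' @param x a `seg_eval_report`.
#' @param ... unused.
#' @method glance seg_eval_report
#' @export
glance.seg_eval_report <- function(x, ...) x$stats
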