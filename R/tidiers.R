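#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transmural profile fit
#'
#' One row per regression term (intercept in degrees, slope in degrees/mm).
#'
#' @param x a [transmural_profile_fit()] object.
#' @param ... unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.transmural_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "depth_mm"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.transmural_fit
#' @return `glance()` returns a one-row tibble with `r.squared` and `nobs`.
#' @export
glance.transmural_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n)
}

#' Tidy a group comparison
#'
#' Returns the comparison table in long broom-style form: one row per
#' metric with estimates for both groups, the percent change and the
#' rank-sum p-value.
#'
#' @param x a [summarize_groups()] result.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x)[, c("metric", "mean_infarcted", "mean_control",
                           "percent_change", "statistic", "p_value")]
}

#' @rdname tidy.group_comparison
#' @return `glance()` returns one row with the mode, group sizes and the
#'   number of metrics at p < 0.05.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(mode = x$mode[1],
                 n_infarcted = x$n_infarcted[1],
                 n_control = x$n_control[1],
                 n_metrics = nrow(x),
                 n_significant = sum(x$p_value < 0.05, na.rm = TRUE))
}
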