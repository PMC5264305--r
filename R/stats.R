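#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U test: exact null enumeration when both samples
#' are small (min(n, m) <= 8) and tie-free, tie-corrected normal
#' approximation with continuity correction otherwise. Identical samples
#' give p = 1.
#'
#' @param x,y numeric samples (nonempty).
#' @return List with `statistic` (U for the first sample) and `p_value`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  if (length(x) == length(y) && all(sort(x) == sort(y)))
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Pearson correlation
#'
#' Standard product-moment correlation; errors on degenerate input
#' (n < 3 or zero variance).
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Percent change relative to a reference
#'
#' 100 (value - reference) / reference, signed; rounding to integer percent
#' is left to presentation.
#'
#' @param value,reference numeric (reference nonzero).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(9.08e-4, 6.33e-4)  # +43.4 -> prints as a 43% increase
#' percent_change(0.24, 0.37)        # -35.1 -> a 35% decrease
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("zero reference: percent change undefined")
  100 * (value - reference) / reference
}

#' Group comparison of segment metrics
#'
#' Compares every metric between infarcted and control segments with the
#' Wilcoxon rank-sum test, in one of two modes: `per_heart` averages each
#' metric within heart first and tests across heart means (the 8-vs-4
#' study design); `per_segment` pools all segment records. Percent change
#' uses the control group as reference. No multiple-testing correction is
#' applied.
#'
#' @param metrics a [segment_metrics()] table covering both statuses, with
#'   a `heart_id` column for `per_heart` mode.
#' @param mode `"per_heart"` or `"per_segment"`.
#' @param metric_cols metrics to compare.
#' @return A `group_comparison` tibble: `metric`, `mean_infarcted`,
#'   `sd_infarcted`, `mean_control`, `sd_control`, `percent_change`,
#'   `statistic`, `p_value`, `mode`, `n_infarcted`, `n_control`.
#' @export
summarize_groups <- function(metrics,
                             mode = c("per_heart", "per_segment"),
                             metric_cols = c(
                               "thickness_mm", "transmurality",
                               "inclination_range_deg", "slope_deg_per_mm",
                               "intercept_deg", "r2", "imbrication_mean_deg",
                               "inclination_incoherency_deg",
                               "imbrication_incoherency_deg",
                               "lh_ratio", "circ_ratio", "rh_ratio")) {
  mode <- match.arg(mode)
  dat <- metrics |>
    dplyr::filter(!.data$excluded,
                  .data$status %in% c("infarcted", "control"))
  for (g in c("infarcted", "control"))
    if (!any(dat$status == g)) stop(sprintf("no %s segments in the table", g))
  metric_cols <- intersect(metric_cols, names(dat))
  if (mode == "per_heart") {
    stopifnot("heart_id" %in% names(dat))
    dat <- dat |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                     ~ mean(.x, na.rm = TRUE)),
                       .by = c("heart_id", "status"))
  }
  rows <- lapply(metric_cols, function(mc) {
    a <- dat[[mc]][dat$status == "infarcted"]
    b <- dat[[mc]][dat$status == "control"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 || length(b) == 0)
      return(tibble::tibble(metric = mc, mean_infarcted = NA_real_,
                            sd_infarcted = NA_real_, mean_control = NA_real_,
                            sd_control = NA_real_, percent_change = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            n_infarcted = length(a), n_control = length(b)))
    ts <- rank_sum_test(a, b)
    tibble::tibble(
      metric = mc,
      mean_infarcted = mean(a), sd_infarcted = sd(a),
      mean_control = mean(b), sd_control = sd(b),
      percent_change = if (mean(b) != 0) percent_change(mean(a), mean(b))
                       else NA_real_,
      statistic = ts$statistic, p_value = ts$p_value,
      n_infarcted = length(a), n_control = length(b))
  })
  out <- dplyr::bind_rows(rows)
  out$mode <- mode
  class(out) <- c("group_comparison", class(out))
  out
}

#' Pairwise Pearson correlations among remodeling metrics
#'
#' Correlates slope, inclination range, wall thickness, inverse wall
#' thickness and scar transmurality across the (non-excluded) infarcted
#' segments - the associations used to attribute the slope increase to wall
#' thinning.
#'
#' @param metrics a [segment_metrics()] table.
#' @param status segment status to correlate within.
#' @return Tibble `var1`, `var2`, `r`, `n`.
#' @export
metric_correlations <- function(metrics, status = "infarcted") {
  dat <- metrics |>
    dplyr::filter(!.data$excluded, .data$status == !!status) |>
    dplyr::mutate(inv_thickness = 1 / .data$thickness_mm)
  vars <- c("slope_deg_per_mm", "inclination_range_deg", "thickness_mm",
            "inv_thickness", "transmurality")
  vars <- intersect(vars, names(dat))
  combos <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    v1 <- dat[[combos[1, i]]]; v2 <- dat[[combos[2, i]]]
    keep <- is.finite(v1) & is.finite(v2)
    tibble::tibble(var1 = combos[1, i], var2 = combos[2, i],
                   r = if (sum(keep) >= 3 && sd(v1[keep]) > 0 &&
                           sd(v2[keep]) > 0)
                     pearson_r(v1[keep], v2[keep]) else NA_real_,
                   n = sum(keep))
  })
  dplyr::bind_rows(rows)
}
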