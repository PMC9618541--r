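# Univariate statistics of the maturation analysis: hemispheric
# lateralization, age trends, and neonate-vs-adult group contrasts.
# Multiple-comparison handling follows the Bonferroni-Dunn convention:
# trend significance is flagged at the divided alpha threshold
# (0.05/6 = 0.008 for six metrics), while contrast p values are also
# reported Bonferroni-multiplied.

#' Lateralization index
#'
#' `LI = (left - right) / (left + right)`; positive values indicate left
#' lateralization. For positive-valued metrics LI lies in `[-1, 1]`.
#'
#' @param left,right tract-mean values (vectorised).
#' @return numeric vector of LI values.
#' @export
lateralization_index <- function(left, right) {
  s <- left + right
  if (any(s == 0)) stop("lateralization undefined: left + right = 0")
  (left - right) / s
}

#' One-sample t test
#'
#' `t = (mean - null) / (SD / sqrt(n))` with `df = n - 1` and a two-sided
#' p value; used to test LI samples against 0.
#'
#' @param values numeric sample, n >= 2.
#' @param null null-hypothesis mean.
#' @return one-row tibble: `estimate`, `t`, `df`, `p`, `n`.
#' @export
one_sample_t <- function(values, null = 0) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: t undefined")
  t <- (mean(values) - null) / (s / sqrt(n))
  tibble::tibble(estimate = mean(values), t = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), n - 1), n = n)
}

#' Pearson age-trend test
#'
#' Pearson correlation between a metric and age with the t statistic from
#' the identity `t = r * sqrt(n - 2) / sqrt(1 - r^2)` (df = n - 2) and a
#' two-sided p value; the significance flag applies the Bonferroni-Dunn
#' divided threshold `alpha / n_tests` (0.05/6 = 0.008 for the six
#' metrics).
#'
#' @param values metric values per subject.
#' @param ages ages per subject (n >= 3).
#' @param n_tests number of tests the threshold corrects for.
#' @param alpha family-wise level.
#' @return one-row tibble: `r`, `t`, `df`, `p`, `threshold`, `significant`.
#' @export
pearson_trend <- function(values, ages, n_tests = 6, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  if (length(ages) != n) stop("values and ages differ in length")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(values, ages)
  t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  thr <- alpha / n_tests
  tibble::tibble(r = r, t = t, df = n - 2, p = p, threshold = thr,
                 significant = p < thr)
}

#' Two-sample group contrast with Cohen's d
#'
#' Pooled-variance two-sided Student's t test (`df = n1 + n2 - 2`) with
#' Bonferroni-multiplied adjusted p and Cohen's d using the pooled SD.
#' Signs follow first-minus-second: `t` and `d` are positive when the
#' first sample's mean is larger. [contrast_analysis()] calls this with
#' the adult group first, so reported d follows the adult-minus-neonate
#' convention; `d_abs` is supplied for magnitude comparisons.
#'
#' @param x,y the two samples (each n >= 2).
#' @param n_tests Bonferroni multiplier for the adjusted p.
#' @return one-row tibble: `t`, `df`, `p`, `p_adj`, `d`, `d_abs`,
#'   `n1`, `n2`.
#' @export
group_contrast <- function(x, y, n_tests = 6) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(x) - mean(y)) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  tibble::tibble(t = t, df = df, p = p, p_adj = min(1, p * n_tests),
                 d = d, d_abs = abs(d), n1 = n1, n2 = n2)
}

cohort_avg <- function(cohort, group = NULL) {
  out <- dplyr::filter(cohort, .data$hemisphere == "avg")
  if (!is.null(group)) out <- out[out$group == group, ]
  if (nrow(out) == 0) stop("no L/R-averaged rows for group ", group %||% "?")
  out
}

#' Age-trend table across bundles and metrics
#'
#' Runs [pearson_trend()] for every bundle x metric of one group's
#' L/R-averaged tract means (the Table-3-style layout: r, t, df, p and
#' the Bonferroni-Dunn flag).
#'
#' @param cohort tidy cohort table ([build_cohort_table()] /
#'   [simulate_cohort_tables()]).
#' @param group which group to test (default `"neonate"`).
#' @inheritParams pearson_trend
#' @return tibble with one row per bundle x metric.
#' @export
trend_analysis <- function(cohort, group = "neonate", n_tests = 6,
                           alpha = 0.05) {
  cohort_avg(cohort, group) |>
    dplyr::group_by(.data$bundle, .data$metric) |>
    dplyr::reframe(pearson_trend(.data$value, .data$age,
                                 n_tests = n_tests, alpha = alpha))
}

#' Neonate-vs-adult contrast table
#'
#' Runs [group_contrast()] (adult first, so d is adult minus neonate) for
#' every bundle x metric of the L/R-averaged tract means — the
#' Table-4-style layout.
#'
#' @param cohort tidy cohort table holding both groups.
#' @inheritParams group_contrast
#' @return tibble with one row per bundle x metric.
#' @export
contrast_analysis <- function(cohort, n_tests = 6) {
  cohort_avg(cohort) |>
    dplyr::group_by(.data$bundle, .data$metric) |>
    dplyr::reframe(group_contrast(.data$value[.data$group == "adult"],
                                  .data$value[.data$group == "neonate"],
                                  n_tests = n_tests))
}

#' Lateralization table
#'
#' Computes the per-subject LI from the left and right tract means for
#' every bundle x metric of one group and tests it against 0 with
#' [one_sample_t()].
#'
#' @param cohort tidy cohort table with `L` and `R` hemisphere rows.
#' @param group which group to test.
#' @return tibble with one row per bundle x metric: mean LI, t, df, p.
#' @export
lateralization_analysis <- function(cohort, group = "neonate") {
  wide <- cohort |>
    dplyr::filter(.data$group == !!group,
                  .data$hemisphere %in% c("L", "R")) |>
    dplyr::select("subject", "bundle", "metric", "hemisphere", "value") |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "value")
  wide |>
    dplyr::mutate(li = lateralization_index(.data$L, .data$R)) |>
    dplyr::group_by(.data$bundle, .data$metric) |>
    dplyr::reframe(one_sample_t(.data$li))
}
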