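# Wilcoxon signed-rank test with Pratt zero handling: zero differences
# participate in the ranking of |d| but are then dropped from the
# statistic. The exact null distribution (computed by dynamic programming)
# is used for n <= 25 when no zeros or ties are present; otherwise a
# normal approximation with the Pratt zero correction, tie correction and
# continuity correction. Reproducible across implementations by
# construction.

# counts of subset-sums of {1..n}: signrank null distribution numerator
.signrank_cache <- new.env(parent = emptyenv())
signrank_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(.signrank_cache[[key]])) return(.signrank_cache[[key]])
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  .signrank_cache[[key]] <- counts  # counts[w + 1] = #subsets summing to w
  counts
}

#' Wilcoxon signed-rank test
#'
#' Paired (or one-sample) signed-rank test of the hypothesis that the
#' differences are symmetric about `mu`. The statistic is `W+`, the sum
#' of ranks of positive differences, with zeros handled by the Pratt
#' method. Two-sided p values come from the exact null distribution for
#' n <= `exact_max` zero/tie-free differences, else from the corrected
#' normal approximation.
#'
#' @param x numeric sample (or differences when `y` is NULL).
#' @param y optional paired sample.
#' @param mu null location of the differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return one-row tibble: `statistic` (W+), `n` (non-zero differences),
#'   `n_zero`, `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0, exact_max = 25) {
  d <- if (is.null(y)) x - mu else {
    if (length(x) != length(y)) stop("paired samples differ in length")
    x - y - mu
  }
  d <- d[is.finite(d)]
  n_all <- length(d)
  if (n_all < 1) stop("no usable differences")
  # Pratt: rank |d| including zeros, then drop zeros from the statistic
  rk <- rank(abs(d))
  nonzero <- d != 0
  n <- sum(nonzero)
  n_zero <- n_all - n
  if (n == 0) stop("all differences are zero")
  w_pos <- sum(rk[nonzero & d > 0])

  ties <- any(duplicated(abs(d[nonzero])))
  if (n <= exact_max && n_zero == 0 && !ties) {
    counts <- signrank_counts(n)
    total <- 2^n
    w <- w_pos
    p_le <- sum(counts[seq_len(w + 1)]) / total
    p_ge <- sum(counts[(w + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    # normal approximation with Pratt zero correction and tie correction
    mu_w <- (n_all * (n_all + 1) - n_zero * (n_zero + 1)) / 4
    tie_tab <- table(rk[nonzero])
    var_w <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu_w - sign(w_pos - mu_w) * 0.5) / sqrt(var_w)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(statistic = w_pos, n = n, n_zero = n_zero, p = p,
                 method = method)
}
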