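# The multivariate maturation index: each neonatal bundle is summarised
# by a six-metric vector (NDI, ODI, FA, MD, AD, RD) and its Mahalanobis
# distance M to the adult reference distribution of the same bundle.
# M is computed in the eigen-decomposition form
#   M^2 = sum_i ((x - mu) . v_i)^2 / lambda_i
# (rotate into the covariance eigenbasis, scale each axis to unit
# variance), with the direct inverse form (x - mu)' Sigma^-1 (x - mu)
# stored as a cross-check; the two are algebraically identical for a
# full-rank covariance, which makes M invariant under any invertible
# linear remap of the metric space — in particular under per-metric
# rescaling, so the very different orders of magnitude of the six
# metrics cannot bias the index. Smaller M means closer to the adult
# stage.

#' The six diffusion metrics entering the maturation index
#'
#' Fixed metric order of the combined DTI + NODDI distance: NDI, ODI, FA,
#' MD, AD, RD.
#' @export
SLF_METRICS <- c("ndi", "odi", "fa", "md", "ad", "rd")

#' Build the adult reference distribution for one bundle
#'
#' Sample mean vector and covariance matrix (n - 1 denominator) of the
#' adults' L/R-averaged metric vectors for one bundle, with the
#' eigen-decomposition stored for the distance computation. Refuses
#' references built from fewer than 8 adults or with a numerically
#' rank-deficient covariance (condition number > 1e10), naming the most
#' collinear metrics in the diagnostic.
#'
#' @param cohort tidy cohort table containing the adult group.
#' @param bundle bundle name (e.g. `"SLF II"`).
#' @param metrics metric names, in fixed order (default the six
#'   DTI + NODDI metrics).
#' @param hemisphere which rows to use (default the L/R-averaged ones).
#' @return an object of class `adult_reference`: `bundle`, `metrics`,
#'   `mu`, `sigma`, eigenvectors `vectors` (columns), eigenvalues
#'   `values`, `n`, `condition`.
#' @export
build_adult_reference <- function(cohort, bundle, metrics = SLF_METRICS,
                                  hemisphere = "avg") {
  wide <- cohort |>
    dplyr::filter(.data$group == "adult", .data$bundle == !!bundle,
                  .data$hemisphere == !!hemisphere,
                  .data$metric %in% metrics) |>
    dplyr::select("subject", "metric", "value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  missing <- setdiff(metrics, names(wide))
  if (length(missing) > 0) {
    stop("adult table lacks metric(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(wide[, metrics])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 8) stop("refusing reference from n = ", n, " adults (need >= 8)")
  mu <- colMeans(X)
  sigma <- stats::cov(X)
  e <- eigen(sigma, symmetric = TRUE)
  cond <- e$values[1] / e$values[length(e$values)]
  if (any(e$values <= 0) || !is.finite(cond) || cond > 1e10) {
    cc <- stats::cov2cor(sigma); diag(cc) <- 0
    worst <- arrayInd(which.max(abs(cc)), dim(cc))
    stop("rank-deficient adult covariance (condition ", format(cond),
         "); most collinear metrics: ", metrics[worst[1]], " ~ ",
         metrics[worst[2]])
  }
  structure(list(bundle = bundle, metrics = metrics, mu = mu, sigma = sigma,
                 vectors = e$vectors, values = e$values, n = n,
                 condition = cond),
            class = "adult_reference")
}

#' @export
print.adult_reference <- function(x, ...) {
  cat("<adult_reference> ", x$bundle, " (n = ", x$n, ")\n", sep = "")
  cat("  metrics: ", paste(x$metrics, collapse = ", "), "\n", sep = "")
  cat("  covariance condition number: ", format(signif(x$condition, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Mahalanobis distance of a metric vector from the adult reference
#'
#' Computed in the eigen form (projections onto the covariance
#' eigenvectors, each squared and scaled by its eigenvalue); the direct
#' inverse form is evaluated as a cross-check and stored in the
#' `"m_direct"` attribute. M >= 0, with M = 0 exactly at the reference
#' mean.
#'
#' Numerical note: both forms are evaluated after standardising each
#' metric by its reference SD (i.e. on the correlation-scaled
#' covariance). M is mathematically invariant under this diagonal remap,
#' and the standardisation keeps the computation stable however wildly
#' the raw metric magnitudes differ (diffusivities ~1e-3 mm^2/s next to
#' order-one fractions).
#'
#' @param x numeric vector (or matrix, one row per subject) of metric
#'   values ordered as `ref$metrics`.
#' @param ref an [build_adult_reference()] object.
#' @return numeric vector of distances, attribute `m_direct` holding the
#'   direct-inverse values.
#' @export
mahalanobis_distance <- function(x, ref) {
  stopifnot(inherits(ref, "adult_reference"))
  if (any(ref$values <= 0)) stop("degenerate reference: eigenvalue <= 0")
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(ref$mu)) {
    stop("x has ", ncol(x), " metrics; reference has ", length(ref$mu))
  }
  s <- sqrt(diag(ref$sigma))
  corr <- ref$sigma / outer(s, s)          # diagonally standardised
  e <- eigen(corr, symmetric = TRUE)
  if (any(e$values <= 0)) stop("degenerate reference: eigenvalue <= 0")
  z <- sweep(sweep(x, 2, ref$mu), 2, s, "/")
  proj <- z %*% e$vectors                  # rotate into the eigenbasis
  m2 <- drop((proj^2) %*% (1 / e$values))
  direct <- rowSums((z %*% solve(corr)) * z)
  structure(sqrt(pmax(m2, 0)), m_direct = sqrt(pmax(direct, 0)))
}

#' Multivariate maturation analysis of the SLF branches
#'
#' The full maturation pipeline on a cohort table containing both groups:
#' per-bundle adult references, per-neonate Mahalanobis distances
#' (smaller = more adult-like), pairwise Wilcoxon signed-rank comparisons
#' of the distances across branches (Bonferroni threshold `alpha`,
#' default 0.01 for the three pairs), Spearman rank correlation of M with
#' PMA per branch, and the branch maturity ranking by mean M (the branch
#' with the largest mean M is the least mature).
#'
#' @param cohort tidy cohort table with `"avg"` hemisphere rows for both
#'   groups.
#' @param metrics metric names used in the distance (default all six).
#' @param bundles bundle names (default the three SLF branches).
#' @param alpha significance threshold for the pairwise Wilcoxon tests.
#' @return an object of class `maturation_result`: tibbles `distances`
#'   (subject, age, bundle, m), `wilcoxon` (pairwise tests), `spearman`
#'   (M-vs-age per bundle), `ranking` (mean M, descending), plus the
#'   `references` list.
#' @export
maturation_analysis <- function(cohort, metrics = SLF_METRICS,
                                bundles = c("SLF I", "SLF II", "SLF III"),
                                alpha = 0.01) {
  refs <- lapply(bundles, build_adult_reference, cohort = cohort,
                 metrics = metrics)
  names(refs) <- bundles

  neo <- cohort |>
    dplyr::filter(.data$group == "neonate", .data$hemisphere == "avg",
                  .data$bundle %in% bundles, .data$metric %in% metrics)
  if (dplyr::n_distinct(neo$subject) < 6) {
    stop("refusing maturation analysis with < 6 neonates")
  }
  distances <- purrr::map_dfr(bundles, function(b) {
    wide <- neo |>
      dplyr::filter(.data$bundle == !!b) |>
      dplyr::select("subject", "age", "metric", "value") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value")
    m <- mahalanobis_distance(as.matrix(wide[, metrics]), refs[[b]])
    tibble::tibble(subject = wide$subject, age = wide$age, bundle = b,
                   m = as.numeric(m))
  })

  pairs <- utils::combn(bundles, 2, simplify = FALSE)
  wilcoxon <- purrr::map_dfr(pairs, function(pr) {
    a <- distances[distances$bundle == pr[1], c("subject", "m")]
    b <- distances[distances$bundle == pr[2], c("subject", "m")]
    common <- intersect(a$subject, b$subject)
    wt <- tryCatch(
      wilcoxon_signed_rank(a$m[match(common, a$subject)],
                           b$m[match(common, b$subject)]),
      error = function(e) tibble::tibble(statistic = NA_real_,
                                         n = length(common), n_zero = NA_integer_,
                                         p = NA_real_, method = "degenerate"))
    tibble::tibble(pair = paste(pr[1], "vs", pr[2]), wt,
                   significant = !is.na(wt$p) & wt$p < alpha)
  })

  spearman <- distances |>
    dplyr::group_by(.data$bundle) |>
    dplyr::summarise(
      rho = suppressWarnings(stats::cor(.data$m, .data$age,
                                        method = "spearman")),
      p = tryCatch(suppressWarnings(stats::cor.test(
        .data$m, .data$age, method = "spearman")$p.value),
        error = function(e) NA_real_),
      .groups = "drop")

  ranking <- distances |>
    dplyr::group_by(.data$bundle) |>
    dplyr::summarise(mean_m = mean(.data$m), sd_m = stats::sd(.data$m),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_m))

  structure(list(distances = distances, wilcoxon = wilcoxon,
                 spearman = spearman, ranking = ranking,
                 references = refs, alpha = alpha, metrics = metrics),
            class = "maturation_result")
}

#' @export
print.maturation_result <- function(x, ...) {
  cat("<maturation_result> ", dplyr::n_distinct(x$distances$subject),
      " neonates, ", nrow(x$ranking), " bundles\n", sep = "")
  cat("  maturity ranking (least mature first):\n")
  for (i in seq_len(nrow(x$ranking))) {
    cat(sprintf("    %-8s mean M = %.2f (SD %.2f)\n", x$ranking$bundle[i],
                x$ranking$mean_m[i], x$ranking$sd_m[i]))
  }
  sig <- x$wilcoxon[x$wilcoxon$significant, ]
  cat("  Wilcoxon (alpha = ", x$alpha, "): ",
      if (nrow(sig)) paste(sig$pair, collapse = "; ") else "none",
      " significant\n", sep = "")
  invisible(x)
}
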