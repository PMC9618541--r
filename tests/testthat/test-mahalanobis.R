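random_reference <- function(p = 6, n = 40, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  sigma <- crossprod(A) / p + diag(p) * 0.1
  mu <- stats::rnorm(p)
  e <- eigen(sigma, symmetric = TRUE)
  structure(list(bundle = "synthetic", metrics = paste0("m", 1:p),
                 mu = mu, sigma = sigma, vectors = e$vectors,
                 values = e$values, n = n,
                 condition = e$values[1] / e$values[p]),
            class = "adult_reference")
}

test_that("adult references are sample moments with stored eigenstructure", {
  tab <- simulate_cohort_tables(cohort_spec(), seed = 81)
  ref <- build_adult_reference(tab, "SLF II")
  expect_identical(ref$n, 40L)
  expect_identical(names(ref$mu), SLF_METRICS)

  # mean/covariance equal direct computation on the wide table
  wide <- cohort_table_wide(tab)
  X <- as.matrix(wide[wide$group == "adult",
                      paste0("SLF II.", SLF_METRICS)])
  expect_equal(unname(ref$mu), unname(colMeans(X)))
  expect_equal(unname(ref$sigma), unname(stats::cov(X)))

  # eigen reconstruction V diag(lambda) V' within 1e-10
  rec <- ref$vectors %*% diag(ref$values) %*% t(ref$vectors)
  expect_lt(max(abs(rec - unname(ref$sigma))), 1e-10)

  # sampling check: covariance entries near the generator covariance at
  # n = 200 (latent-factor structure: cov = D (lam^2 dir dir' + (1-lam^2) I) D)
  big <- simulate_cohort_tables(cohort_spec(n_adult = 200), seed = 82)
  refb <- build_adult_reference(big, "SLF I")
  p <- default_cohort_params()
  pI <- p[p$bundle == "SLF I", ]
  pI <- pI[match(SLF_METRICS, pI$metric), ]
  sd_tot <- sqrt(pI$adult_sd^2 + (0.15 * pI$adult_sd)^2 / 2)
  lam2 <- 0.6^2
  expected <- diag(pI$dir) %*%
    (lam2 * outer(rep(1, 6), rep(1, 6)) + diag(6) * (1 - lam2)) %*%
    diag(pI$dir)
  expected <- expected * outer(pI$adult_sd, pI$adult_sd)
  diag(expected) <- sd_tot^2
  # pooled z-ish bound: each entry within ~4 SE of its target
  se <- sqrt((expected^2 + outer(diag(expected), diag(expected))) / 200)
  expect_true(all(abs(refb$sigma - expected) < 4.5 * se))

  # degenerate references are refused with a diagnostic
  degen <- tab
  degen$value[degen$metric == "rd"] <-
    degen$value[degen$metric == "md"]    # rd duplicates md
  expect_error(build_adult_reference(degen, "SLF I"), "collinear")
  few <- dplyr::filter(tab, !(.data$group == "adult" &
                                .data$subject > "a007"))
  expect_error(build_adult_reference(few, "SLF I"), ">= 8")
})

test_that("eigen and direct-inverse distances agree (the two stated forms)", {
  set.seed(83)
  for (i in 1:50) {
    ref <- random_reference(seed = 1000 + i)
    x <- ref$mu + stats::rnorm(6, sd = 2)
    m <- mahalanobis_distance(x, ref)
    expect_equal(as.numeric(m), attr(m, "m_direct"), tolerance = 1e-8)
    # independent oracle
    expect_equal(as.numeric(m),
                 sqrt(stats::mahalanobis(x, ref$mu, ref$sigma)),
                 tolerance = 1e-8)
  }
})

test_that("distance behaves geometrically", {
  ref <- random_reference(seed = 84)
  # x = mu -> M = 0
  expect_equal(as.numeric(mahalanobis_distance(ref$mu, ref)), 0)

  # 1-D reduction: x = 2, mu = 0, sigma^2 = 4 -> M = 1
  ref1 <- structure(list(bundle = "b", metrics = "m", mu = 0,
                         sigma = matrix(4), vectors = matrix(1),
                         values = 4, n = 10, condition = 1),
                    class = "adult_reference")
  expect_equal(as.numeric(mahalanobis_distance(2, ref1)), 1)

  # identity covariance: Euclidean distance (3-4-5 triangle)
  refI <- structure(list(bundle = "b", metrics = paste0("m", 1:6),
                         mu = rep(0, 6), sigma = diag(6),
                         vectors = diag(6), values = rep(1, 6), n = 10,
                         condition = 1),
                    class = "adult_reference")
  expect_equal(as.numeric(mahalanobis_distance(c(3, 4, 0, 0, 0, 0), refI)),
               5)

  # homogeneity: scaling the displacement scales M linearly
  ref <- random_reference(seed = 85)
  x <- ref$mu + stats::rnorm(6)
  m1 <- as.numeric(mahalanobis_distance(x, ref))
  for (c_ in c(0, 0.5, 2, 10)) {
    mc <- as.numeric(mahalanobis_distance(ref$mu + c_ * (x - ref$mu), ref))
    expect_equal(mc, c_ * m1, tolerance = 1e-10)
  }
})

test_that("M is invariant under metric rescaling and linear remaps", {
  ref <- random_reference(seed = 86)
  set.seed(87)
  X <- matrix(stats::rnorm(5 * 6), 5) + matrix(ref$mu, 5, 6, byrow = TRUE)
  m0 <- as.numeric(mahalanobis_distance(X, ref))

  remap_reference <- function(ref, A, shift = 0) {
    sigma <- A %*% ref$sigma %*% t(A)
    e <- eigen(sigma, symmetric = TRUE)
    structure(list(bundle = ref$bundle, metrics = ref$metrics,
                   mu = as.numeric(A %*% ref$mu + shift), sigma = sigma,
                   vectors = e$vectors, values = e$values, n = ref$n,
                   condition = e$values[1] / e$values[6]),
              class = "adult_reference")
  }

  # per-metric rescaling (e.g. diffusivities quoted in different units)
  D <- diag(c(1000, 1, 0.01, 7, 1, 100))
  mD <- as.numeric(mahalanobis_distance(X %*% t(D), remap_reference(ref, D)))
  expect_equal(mD, m0, tolerance = 1e-8)

  # arbitrary invertible affine remap of the 6-metric space
  A <- matrix(stats::rnorm(36), 6) + diag(6) * 2
  shift <- stats::rnorm(6)
  mA <- as.numeric(mahalanobis_distance(
    X %*% t(A) + matrix(shift, 5, 6, byrow = TRUE),
    remap_reference(ref, A, shift)))
  expect_equal(mA, m0, tolerance = 1e-8)
})

test_that("maturation analysis ranks branches and tracks age", {
  tab <- simulate_cohort_tables(cohort_spec(), seed = 88)
  mat <- maturation_analysis(tab)

  # generator makes SLF II the least mature: largest mean M, significant
  # against both other branches at the Bonferroni threshold
  expect_identical(mat$ranking$bundle[1], "SLF II")
  expect_true(all(mat$wilcoxon$significant[grepl("SLF II vs|vs SLF II$",
                                                 mat$wilcoxon$pair)]))

  # offsets shrink toward the adult reference with age -> M falls with PMA
  expect_true(all(mat$spearman$rho < 0))

  # neonates equal to the adult means give M = 0 everywhere
  adult_mean <- tab |>
    dplyr::filter(.data$group == "adult", .data$hemisphere == "avg") |>
    dplyr::group_by(.data$bundle, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  clones <- purrr::map_dfr(sprintf("c%02d", 1:10), function(s) {
    dplyr::mutate(adult_mean, subject = s, group = "neonate", age = 40,
                  hemisphere = "avg")
  })
  degenerate <- dplyr::bind_rows(
    dplyr::filter(tab, .data$group == "adult"), clones)
  mat0 <- maturation_analysis(degenerate)
  expect_equal(mat0$distances$m, rep(0, 30), tolerance = 1e-8)
  expect_true(all(is.na(mat0$wilcoxon$p)))      # no ranking possible
  expect_false(any(mat0$wilcoxon$significant))

  # tidy/glance accessors
  expect_identical(nrow(tidy(mat)), 120L)       # 40 neonates x 3 bundles
  expect_identical(nrow(glance(mat)), 3L)
  expect_error(
    maturation_analysis(dplyr::filter(
      tab, .data$group == "adult" | .data$subject %in%
        sprintf("n%03d", 1:4))), "< 6 neonates")
})
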