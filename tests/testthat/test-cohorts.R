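test_that("cohort spec validates its stated world", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(neonate_age_range = c(30, 44)))
  expect_error(cohort_spec(adult_age_range = c(22, 40)))
  p <- default_cohort_params()
  expect_identical(nrow(p), 18L)  # 3 bundles x 6 metrics

  # SLF II sits farther from the adult mean than SLF I/III, metric-wise
  gap <- function(b) abs(p$neo_intercept[p$bundle == b] -
                           p$adult_mean[p$bundle == b])
  expect_true(all(gap("SLF II") > gap("SLF I")))
  expect_identical(gap("SLF I"), gap("SLF III"))
})

test_that("table generator reproduces the requested moments", {
  # group mean of generated tract means within 3 SE of the intercept
  spec <- cohort_spec(n_neonate = 200, n_adult = 200)
  tab <- simulate_cohort_tables(spec, seed = 51)
  p <- spec$params
  for (r in c(1, 8, 15)) {
    row <- p[r, ]
    vals <- tab$value[tab$group == "adult" & tab$bundle == row$bundle &
                        tab$metric == row$metric & tab$hemisphere == "avg"]
    se <- row$adult_sd / sqrt(length(vals))
    expect_lt(abs(mean(vals) - row$adult_mean), 3.5 * se)
  }

  # empirical between-subject SD within 20% of the spec at n = 200
  for (r in c(2, 10)) {
    row <- p[r, ]
    vals <- tab$value[tab$group == "adult" & tab$bundle == row$bundle &
                        tab$metric == row$metric & tab$hemisphere == "avg"]
    expect_lt(abs(stats::sd(vals) - row$adult_sd) / row$adult_sd, 0.20)
  }

  # neonate NDI mean near the intercept at the reference age
  ndi <- tab[tab$group == "neonate" & tab$bundle == "SLF I" &
               tab$metric == "ndi" & tab$hemisphere == "avg", ]
  centred <- ndi$value - p$neo_slope[p$bundle == "SLF I" &
                                       p$metric == "ndi"] * (ndi$age - 40)
  expect_lt(abs(mean(centred) -
                  p$neo_intercept[p$bundle == "SLF I" & p$metric == "ndi"]),
            3.5 * p$neo_sd[p$bundle == "SLF I" & p$metric == "ndi"] /
              sqrt(200))
})

test_that("positive NDI slope yields positive sample age trends", {
  # Monte-Carlo: r(NDI, PMA) > 0 at n = 40 in >= 99% of replicates
  hits <- vapply(1:200, function(s) {
    tab <- simulate_cohort_tables(cohort_spec(n_adult = 1), seed = 1000 + s)
    ndi <- tab[tab$group == "neonate" & tab$bundle == "SLF I" &
                 tab$metric == "ndi" & tab$hemisphere == "avg", ]
    stats::cor(ndi$value, ndi$age) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("tract-mean regression recovers the generator slope", {
  tab <- simulate_cohort_tables(cohort_spec(), seed = 53)
  ndi <- tab[tab$group == "neonate" & tab$bundle == "SLF II" &
               tab$metric == "ndi" & tab$hemisphere == "avg", ]
  fit <- stats::lm(value ~ age, data = ndi)
  slope <- default_cohort_params()$neo_slope[
    default_cohort_params()$bundle == "SLF II" &
      default_cohort_params()$metric == "ndi"]
  expect_lt(abs(stats::coef(fit)["age"] - slope),
            2 * summary(fit)$coefficients["age", "Std. Error"])
})

test_that("volume generator paints bundle corridors recoverable by sampling", {
  spec <- cohort_spec(n_neonate = 2, n_adult = 1)
  lay <- make_phantom(c(40, 40, 40))
  sim <- simulate_cohorts(spec, lay, seed = 54)
  expect_identical(nrow(sim$subjects), 3L)
  expect_length(sim$volumes, 3)
  expect_setequal(names(sim$volumes[[1]]),
                  c("ndi", "odi", "fa", "md", "ad", "rd"))

  # sampling the subject's own corridor recovers the painted value to
  # within the voxel noise of the corridor mean
  centre <- simulate_bundle(lay, c("PaL", "SFgL"), n = 30, jitter = 0.5,
                            seed = 55)
  sid <- sim$subjects$subject[1]
  truth <- sim$means$value[sim$means$subject == sid &
                             sim$means$bundle == "SLF I" &
                             sim$means$metric == "fa"]
  got <- as.numeric(tract_mean(sim$volumes[[1]]$fa, centre))
  expect_lt(abs(got - truth), 0.02)

  # zero slopes and zero subject variation -> identical noise-free maps
  p0 <- default_cohort_params()
  p0$neo_slope <- 0
  p0$neo_sd <- 1e-12
  p0$adult_sd <- 1e-12
  p0$voxel_sd <- 1e-12
  spec0 <- cohort_spec(n_neonate = 2, n_adult = 1, params = p0)
  sim0 <- simulate_cohorts(spec0, lay, seed = 56)
  expect_equal(sim0$volumes[[1]]$fa$data, sim0$volumes[[2]]$fa$data,
               tolerance = 1e-6)
})
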