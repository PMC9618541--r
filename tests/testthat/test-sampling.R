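test_that("streamline sampling interpolates trilinearly", {
  # constant volume: every sample equals the constant
  v <- metric_volume(array(4.2, c(6, 6, 6)))
  s <- rbind(c(1.3, 2.7, 3.1), c(2.2, 2.9, 3.5), c(3.1, 3.3, 4.0))
  expect_equal(sample_along_streamline(v, s), rep(4.2, 3))

  # vertex exactly on a voxel centre returns the stored value
  set.seed(21)
  v <- random_volume(c(5, 5, 5), seed = 21)
  idx <- c(2, 3, 1)
  w <- drop(voxel_to_world(v, matrix(idx, 1)))
  got <- sample_along_streamline(v, rbind(w, w + 1e-9))[1]
  expect_equal(got, v$data[3, 4, 2], tolerance = 1e-6)

  # volume linear in world x, straight streamline along x: sampled values
  # linear, mean equals the midpoint value (trilinear preserves affine
  # fields)
  shape <- c(8, 4, 4)
  aff <- diag(c(2, 2, 2, 1))
  xw <- voxel_to_world(metric_volume(array(0, shape), aff),
                       as.matrix(expand.grid(0:7, 0:3, 0:3)))[, 1]
  lin <- metric_volume(array(3 * xw, shape), aff)
  sl <- cbind(seq(1, 11, by = 0.7), 3.2, 2.8)
  vals <- sample_along_streamline(lin, sl)
  expect_equal(vals, 3 * sl[, 1])
  expect_equal(mean(vals), 3 * mean(range(sl[, 1])), tolerance = 1e-10)

  # out-of-grid vertices yield NA; degenerate streamline errors
  out <- sample_along_streamline(lin, rbind(c(-50, 0, 0), c(3, 3, 3)))
  expect_true(is.na(out[1]) && !is.na(out[2]))
  expect_error(sample_along_streamline(lin, matrix(1, 1, 3)), "degenerate")
})

test_that("tract means are point-weighted over all vertices", {
  # two streamlines sampling {1,1} and {4,4,4,4}: point-weighted mean 3.0
  v <- metric_volume(array(rep(rep(c(1, 4), each = 4), times = 16),
                           c(8, 4, 4)))            # x < 4 -> 1, x >= 4 -> 4
  s1 <- rbind(c(1, 1, 1), c(2, 2, 2))              # in the value-1 half
  s2 <- cbind(c(4.5, 5, 5.5, 6), 2, 2)             # in the value-4 half
  bundle <- tractogram(list(s1, s2))
  expect_equal(as.numeric(tract_mean(v, bundle)), 3.0)
  expect_equal(as.numeric(tract_mean(v, bundle, weight = "streamline")),
               2.5)

  # constant volume: any bundle gives the constant
  vc <- metric_volume(array(7, c(6, 6, 6)))
  trk <- random_tractogram(4, seed = 31)
  trk <- tractogram(lapply(trk$streamlines, function(s) {
    sweep(s %% 4, 2, c(1, 1, 1), "+")
  }))
  expect_equal(as.numeric(tract_mean(vc, trk)), 7)

  # reordering and reversing streamlines leaves the mean unchanged
  v <- random_volume(c(6, 6, 6), seed = 32)
  trk2 <- tractogram(lapply(1:5, function(i) {
    matrix(stats::runif(18, 0.5, 4.5), ncol = 3) %*% v$affine[1:3, 1:3] +
      matrix(v$affine[1:3, 4], 6, 3, byrow = TRUE)
  }))
  m <- as.numeric(tract_mean(v, trk2))
  perm <- tractogram(trk2$streamlines[c(3, 1, 5, 2, 4)])
  rev_ <- tractogram(lapply(trk2$streamlines,
                            function(s) s[nrow(s):1, , drop = FALSE]))
  expect_equal(as.numeric(tract_mean(v, perm)), m)
  expect_equal(as.numeric(tract_mean(v, rev_)), m)

  # oracle equivalence: brute-force loop over every vertex
  brute <- mean(unlist(lapply(trk2$streamlines, function(s) {
    apply(s, 1, function(p) {
      sample_along_streamline(v, rbind(p, p + 1e-9))[1]
    })
  })), na.rm = TRUE)
  expect_equal(m, brute, tolerance = 1e-9)

  # empty bundle and all-outside bundle are explicit errors
  expect_error(tract_mean(v, tractogram()), "empty bundle")
  far <- tractogram(list(rbind(c(900, 900, 900), c(910, 910, 910))))
  expect_error(tract_mean(v, far), "outside")
})

test_that("sampled noisy constants converge to the constant", {
  set.seed(33)
  shape <- c(20, 20, 20)
  v <- metric_volume(array(5 + stats::rnorm(prod(shape), sd = 0.5), shape))
  big <- tractogram(lapply(1:200, function(i) {
    start <- stats::runif(3, 2, 8)
    sweep(matrix(stats::runif(30, 0, 10), ncol = 3), 2, start, "+")
  }))
  expect_lt(abs(as.numeric(tract_mean(v, big)) - 5), 0.05)
})

test_that("cohort tables assemble per-hemisphere and averaged rows", {
  lay <- make_phantom(c(40, 40, 40))
  # one subject, two metrics, tiny dissection: L and R copies of a bundle
  bL <- simulate_bundle(lay, c("PaL", "SFgL"), n = 5, seed = 41)
  bR <- simulate_bundle(lay, c("PaR", "SFgR"), n = 5, seed = 41)
  subjects <- tibble::tibble(subject = "n001", group = "neonate", age = 40)
  dissections <- list(list("SLF I L" = bL, "SLF I R" = bR))
  metrics <- list(list(
    fa = metric_volume(array(0.3, lay$shape), lay$affine),
    ndi = metric_volume(array(0.25, lay$shape), lay$affine)
  ))
  tab <- build_cohort_table(subjects, dissections, metrics)
  expect_setequal(tab$hemisphere, c("L", "R", "avg"))
  expect_identical(nrow(tab), 6L)   # 2 metrics x (L, R, avg)

  # constant volumes: averaged value equals either hemisphere
  avg <- tab$value[tab$hemisphere == "avg" & tab$metric == "fa"]
  expect_equal(avg, 0.3)
  expect_equal(tab$value[tab$hemisphere == "L" & tab$metric == "fa"], 0.3)

  # an empty bundle drops that subject's rows for the bundle, with a note
  dissections2 <- list(list("SLF I L" = bL, "SLF I R" = tractogram()))
  expect_message(
    tab2 <- build_cohort_table(subjects, dissections2, metrics),
    "empty bundle")
  expect_false("R" %in% tab2$hemisphere)
  expect_false("avg" %in% tab2$hemisphere)  # needs both hemispheres
})

test_that("the wide cohort layout has one row per subject", {
  tab <- simulate_cohort_tables(cohort_spec(), seed = 42)
  wide <- cohort_table_wide(tab)
  expect_identical(nrow(wide), 80L)               # 40 neonates + 40 adults
  expect_identical(sum(wide$group == "neonate"), 40L)
  metric_cols <- setdiff(names(wide), c("subject", "group", "age"))
  expect_length(metric_cols, 18)                  # 3 bundles x 6 metrics
})
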