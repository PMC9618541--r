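# Two-cohort generators with the statistical structure the maturation
# analysis assumes: neonatal tract metrics drift linearly toward adult
# values over 37-44 weeks PMA (NDI/FA rising, MD/RD falling, AD/ODI
# nearly flat), adults sit at distinct means with no age trend, and the
# SLF II branch lags the other two. A shared per-subject "maturity" latent
# factor induces realistic cross-metric covariance, so the adult 6x6
# covariance matrix is full rank but far from diagonal.

#' Generative specification for the synthetic cohorts
#'
#' Defaults state the emulated world: 40 neonates scanned at 37-44 weeks
#' PMA, 40 adults aged 22-35 years, six metrics per bundle with neonatal
#' intercepts/slopes chosen to reproduce the qualitative trends of the
#' real cohorts (strong positive NDI/FA age trends, negative MD/RD, flat
#' AD/ODI, large neonate-adult offsets in everything but ODI) and an
#' SLF II branch whose offset from the adult reference is scaled
#' `slf2_lag` times farther than SLF I/III, making it the least mature
#' branch.
#'
#' @param n_neonate,n_adult cohort sizes.
#' @param neonate_age_range PMA weeks, within `[37, 44]`.
#' @param adult_age_range years, within `[22, 35]`.
#' @param age_dist `"uniform"` (default; maximises trend-estimation power)
#'   or `"gaussian"` (scan-age mean 39.89, SD 2.08 weeks, truncated to the
#'   range, emulating the real cohort).
#' @param slf2_lag multiplier (> 1) on the SLF II neonate-to-adult offset
#'   (default 2: the SLF II offset sits twice as far from the adult
#'   reference, in covariance-whitened units, as SLF I/III).
#' @param latent_loading correlation loading of the shared per-subject
#'   maturity factor, in `[0, 1)`.
#' @param hemi_sd hemisphere-specific noise as a fraction of the
#'   between-subject SD (no systematic left/right asymmetry).
#' @param params optional replacement for the per-bundle, per-metric
#'   parameter table (see [default_cohort_params()]).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_neonate = 40, n_adult = 40,
                        neonate_age_range = c(37, 44),
                        adult_age_range = c(22, 35),
                        age_dist = c("uniform", "gaussian"),
                        slf2_lag = 2, latent_loading = 0.6,
                        hemi_sd = 0.15, params = NULL) {
  age_dist <- match.arg(age_dist)
  stopifnot(n_neonate >= 1, n_adult >= 1,
            neonate_age_range[1] >= 37, neonate_age_range[2] <= 44,
            adult_age_range[1] >= 22, adult_age_range[2] <= 35,
            latent_loading >= 0, latent_loading < 1)
  if (is.null(params)) params <- default_cohort_params(slf2_lag)
  stopifnot(all(params$neo_sd > 0), all(params$adult_sd > 0),
            all(params$voxel_sd > 0))
  structure(list(n_neonate = n_neonate, n_adult = n_adult,
                 neonate_age_range = neonate_age_range,
                 adult_age_range = adult_age_range,
                 age_dist = age_dist, ref_age = 40,
                 latent_loading = latent_loading, hemi_sd = hemi_sd,
                 params = params),
            class = "cohort_spec")
}

#' Per-bundle, per-metric generative parameters
#'
#' Neonatal intercepts are stated at the reference age (40 weeks PMA);
#' slopes are per week. Diffusivities in mm^2/s. `dir` is the loading
#' sign of the shared maturity factor (maturation raises FA/NDI and
#' lowers the diffusivities).
#'
#' @param slf2_lag multiplier on the SLF II neonate-to-adult offset.
#' @return tibble with one row per bundle x metric.
#' @export
default_cohort_params <- function(slf2_lag = 2) {
  base <- tibble::tribble(
    ~metric, ~neo_intercept, ~neo_slope, ~neo_sd, ~adult_mean, ~adult_sd, ~dir,
    "ndi", 0.25,     0.008,     0.020,    0.55,    0.025,  1,
    "odi", 0.15,     0.000,     0.020,    0.18,    0.020, -1,
    "fa",  0.22,     0.005,     0.015,    0.45,    0.020,  1,
    "md",  1.30e-3, -0.020e-3,  0.040e-3, 0.72e-3, 0.030e-3, -1,
    "ad",  1.55e-3, -0.005e-3,  0.050e-3, 1.10e-3, 0.040e-3, -1,
    "rd",  1.15e-3, -0.020e-3,  0.045e-3, 0.53e-3, 0.035e-3, -1
  )
  out <- purrr::map_dfr(c("SLF I", "SLF II", "SLF III"), function(b) {
    p <- base
    if (b == "SLF II") {
      # scale the neonate-to-adult offset: SLF II lags the other branches
      p$neo_intercept <- p$adult_mean +
        slf2_lag * (p$neo_intercept - p$adult_mean)
    }
    p$bundle <- b
    p
  })
  out$voxel_sd <- 2 * out$neo_sd
  out[, c("bundle", "metric", "neo_intercept", "neo_slope", "neo_sd",
          "adult_mean", "adult_sd", "voxel_sd", "dir")]
}

draw_ages <- function(n, range, dist, mean = 39.89, sd = 2.08) {
  if (dist == "uniform") return(stats::runif(n, range[1], range[2]))
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
}

# per-subject bundle x metric means: intercept + slope*(age - ref) +
# correlated subject effect (shared maturity latent + independent residual)
draw_subject_means <- function(spec, group, ages) {
  p <- spec$params
  lam <- spec$latent_loading
  n <- length(ages)
  u <- stats::rnorm(n)                    # shared maturity factor
  purrr::map_dfr(seq_len(nrow(p)), function(r) {
    row <- p[r, ]
    if (group == "neonate") {
      centre <- row$neo_intercept + row$neo_slope * (ages - spec$ref_age)
      sdv <- row$neo_sd
    } else {
      centre <- rep(row$adult_mean, n)
      sdv <- row$adult_sd
    }
    z <- stats::rnorm(n)
    eff <- (lam * row$dir * u + sqrt(1 - lam^2) * z) * sdv
    tibble::tibble(subject = seq_len(n), age = ages,
                   bundle = row$bundle, metric = row$metric,
                   value = centre + eff)
  })
}

#' Simulate neonate and adult cohort tables directly
#'
#' Draws tract-mean tables with the generative structure of
#' [cohort_spec()] without going through volumes — the fast path used for
#' Monte-Carlo validation of the statistics layer. Left/right hemisphere
#' values are the subject mean plus independent hemisphere noise (no
#' systematic lateralization), and `"avg"` rows are their arithmetic mean.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return tidy cohort tibble as from [build_cohort_table()] (without the
#'   sampling-count columns).
#' @export
simulate_cohort_tables <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  out <- purrr::map_dfr(c("neonate", "adult"), function(grp) {
    n <- if (grp == "neonate") spec$n_neonate else spec$n_adult
    rng <- if (grp == "neonate") spec$neonate_age_range else
      spec$adult_age_range
    ages <- draw_ages(n, rng, spec$age_dist)
    means <- draw_subject_means(spec, grp, ages)
    means$subject <- paste0(substr(grp, 1, 1), sprintf("%03d", means$subject))
    means$group <- grp
    sd_col <- if (grp == "neonate") "neo_sd" else "adult_sd"
    subj_sd <- spec$params[[sd_col]][match(paste(means$bundle, means$metric),
                                           paste(spec$params$bundle,
                                                 spec$params$metric))]
    hemi <- purrr::map_dfr(c("L", "R"), function(h) {
      x <- means
      x$hemisphere <- h
      # hemisphere noise scales with the between-subject SD; no systematic
      # left/right asymmetry
      x$value <- x$value + stats::rnorm(nrow(x), sd = spec$hemi_sd * subj_sd)
      x
    })
    avg <- hemi |>
      dplyr::group_by(.data$subject, .data$group, .data$age, .data$bundle,
                      .data$metric) |>
      dplyr::summarise(hemisphere = "avg", value = mean(.data$value),
                       .groups = "drop")
    dplyr::bind_rows(hemi, avg)
  })
  dplyr::select(out, "subject", "group", "age", "bundle", "hemisphere",
                "metric", "value") |>
    dplyr::arrange(.data$group, .data$subject, .data$bundle,
                   .data$hemisphere, .data$metric)
}

# voxel mask of all voxels within `radius` voxels of a world-mm polyline
mask_from_polyline <- function(layout, pts, radius = 2L) {
  vol <- layout$volume
  step <- min(sqrt(colSums(vol$affine[1:3, 1:3]^2))) / 2
  dense <- supersample_polyline(pts, step)
  idx <- floor(world_to_voxel(vol, dense) + 0.5)
  d <- dim(vol$data)
  mask <- array(FALSE, d)
  off <- seq(-radius, radius)
  for (dx in off) for (dy in off) for (dz in off) {
    if (dx^2 + dy^2 + dz^2 > radius^2) next
    i <- idx[, 1] + dx; j <- idx[, 2] + dy; k <- idx[, 3] + dz
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    mask[cbind(i[ok], j[ok], k[ok]) + 1] <- TRUE
  }
  mask
}

#' Simulate per-subject metric volumes for two cohorts
#'
#' The volume-level generator behind the end-to-end pipeline test: each
#' subject receives one 3-D volume per metric in which the voxels of each
#' bundle corridor (the phantom bundle centerline dilated by
#' `corridor_radius` voxels) carry that subject's bundle metric value plus
#' independent voxel noise, over a background of the across-bundle mean.
#'
#' @param spec a [cohort_spec()].
#' @param layout a [make_phantom()] layout.
#' @param protocol routing protocol for the bundle corridors.
#' @param corridor_radius dilation radius in voxels.
#' @param seed integer RNG seed.
#' @return list with `subjects` (tibble: subject, group, age), `volumes`
#'   (per-subject named list of six metric volumes), `means` (the
#'   noise-free per-subject bundle x metric means used to paint the
#'   volumes) and `masks` (per-bundle corridor masks).
#' @export
simulate_cohorts <- function(spec = cohort_spec(), layout = make_phantom(),
                             protocol = "neonate", corridor_radius = 2L,
                             seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  rules <- slf_rules(protocol)
  centerlines <- lapply(seq_len(nrow(rules)), function(i) {
    simulate_bundle(layout, rules$include[[i]], n = 1, jitter = 0,
                    seed = 1L)$streamlines[[1]]
  })
  masks <- lapply(centerlines, mask_from_polyline, layout = layout,
                  radius = corridor_radius)
  names(masks) <- rules$name

  groups <- c(rep("neonate", spec$n_neonate), rep("adult", spec$n_adult))
  ages <- c(draw_ages(spec$n_neonate, spec$neonate_age_range, spec$age_dist),
            draw_ages(spec$n_adult, spec$adult_age_range, "uniform"))
  subjects <- tibble::tibble(
    subject = sprintf("%s%03d", substr(groups, 1, 1),
                      c(seq_len(spec$n_neonate), seq_len(spec$n_adult))),
    group = groups, age = ages
  )

  means_n <- draw_subject_means(spec, "neonate",
                                ages[groups == "neonate"])
  means_a <- draw_subject_means(spec, "adult", ages[groups == "adult"])
  means_a$subject <- means_a$subject + spec$n_neonate
  means <- dplyr::bind_rows(means_n, means_a)
  means$subject <- subjects$subject[means$subject]

  metrics <- unique(spec$params$metric)
  shape <- layout$shape
  volumes <- lapply(seq_len(nrow(subjects)), function(i) {
    sm <- means[means$subject == subjects$subject[i], ]
    out <- lapply(metrics, function(m) {
      mm <- sm[sm$metric == m, ]
      vox_sd <- spec$params$voxel_sd[spec$params$metric == m][1]
      arr <- array(mean(mm$value), shape)
      for (b in names(masks)) {
        # per-hemisphere corridors carry the bundle value ("SLF I L" ->
        # bundle "SLF I")
        bname <- sub(" [LR]$", "", b)
        arr[masks[[b]]] <- mm$value[mm$bundle == bname]
      }
      arr <- arr + array(stats::rnorm(prod(shape), sd = vox_sd), shape)
      metric_volume(arr, layout$affine)
    })
    stats::setNames(out, metrics)
  })
  names(volumes) <- subjects$subject

  list(subjects = subjects, volumes = volumes, means = means, masks = masks)
}
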