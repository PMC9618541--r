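# Tract-mean extraction: trilinear sampling of metric volumes at streamline
# vertices, reduced to one unweighted mean per subject x bundle x metric
# over all sampling points of all streamlines (so longer streamlines weigh
# more). The streamline-weighted mean is available as an option.

trilinear_at <- function(volume, idx) {
  d <- dim(volume$data)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  # clamp the base corner so points on the upper face interpolate (f = 1)
  i0 <- pmin(floor(idx), rep(d - 2L, each = nrow(idx)))
  i0 <- pmax(i0, 0L)
  f <- idx - i0
  out <- rep(NA_real_, nrow(idx))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  f <- f[inside, , drop = FALSE]
  lin <- function(dx, dy, dz) {
    volume$data[(i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) +
                  d[2] * (i0[, 3] + dz)) + 1]
  }
  val <-
    lin(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    lin(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    lin(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    lin(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    lin(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    lin(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- val
  out
}

#' Sample a metric volume along a streamline
#'
#' Returns one value per vertex by trilinear interpolation in continuous
#' voxel-index space. Vertices outside the interpolable grid yield `NA`.
#'
#' @param volume a 3-D [metric_volume()].
#' @param streamline n x 3 matrix of world-mm vertices, n >= 2.
#' @param method `"trilinear"` (default, matching the sampling tool the
#'   field uses) or `"nearest"`.
#' @return numeric vector of length n.
#' @export
sample_along_streamline <- function(volume, streamline,
                                    method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  streamline <- rbind_points(streamline)
  if (nrow(streamline) < 2) {
    stop("degenerate streamline: need >= 2 vertices")
  }
  idx <- world_to_voxel(volume, streamline)
  if (method == "nearest") {
    d <- dim(volume$data)
    i <- floor(idx + 0.5)
    ok <- i[, 1] >= 0 & i[, 1] < d[1] & i[, 2] >= 0 & i[, 2] < d[2] &
          i[, 3] >= 0 & i[, 3] < d[3]
    out <- rep(NA_real_, nrow(i))
    out[ok] <- volume$data[i[ok, 1] + d[1] * (i[ok, 2] + d[2] * i[ok, 3]) + 1]
    return(out)
  }
  trilinear_at(volume, idx)
}

#' Tract-mean metric value of a bundle
#'
#' Unweighted mean over all sampling points of all streamlines (the
#' point-weighted mean: streamlines with more vertices contribute more).
#' Out-of-grid vertices are dropped and counted, never zero-filled. An
#' empty bundle, or one with no in-grid vertex, is an explicit error.
#'
#' @param volume a 3-D [metric_volume()].
#' @param bundle a [tractogram()].
#' @param weight `"point"` (default) or `"streamline"` (mean of per-
#'   streamline means).
#' @param method interpolation passed to [sample_along_streamline()].
#' @return scalar mean; attributes `n_points` (used) and `n_dropped`.
#' @export
tract_mean <- function(volume, bundle, weight = c("point", "streamline"),
                       method = "trilinear") {
  weight <- match.arg(weight)
  if (length(bundle) == 0) stop("empty bundle: no streamlines to sample")
  vals <- lapply(bundle$streamlines, sample_along_streamline,
                 volume = volume, method = method)
  flat <- unlist(vals)
  n_dropped <- sum(is.na(flat))
  if (all(is.na(flat))) stop("all sampling points fall outside the grid")
  m <- if (weight == "point") {
    mean(flat, na.rm = TRUE)
  } else {
    mean(vapply(vals, mean, numeric(1), na.rm = TRUE), na.rm = TRUE)
  }
  structure(m, n_points = sum(!is.na(flat)), n_dropped = n_dropped)
}

#' Build the subject x bundle x metric cohort table
#'
#' Samples every metric volume along every dissected bundle of every
#' subject and reduces to tract means, emitting per-hemisphere rows plus
#' the left/right-averaged rows (arithmetic mean of the two hemisphere
#' tract means) used by the downstream statistics. Subjects with an empty
#' bundle are excluded from that bundle's rows (with a message).
#'
#' @param subjects tibble with columns `subject`, `group` (`"neonate"` or
#'   `"adult"`), `age` (PMA weeks for neonates, years for adults).
#' @param dissections per-subject named list of six bundle
#'   [tractogram()]s, names like `"SLF I L"` (as from [dissect_slf()]).
#' @param metrics per-subject named list of 3-D metric volumes (names are
#'   metric names, e.g. `fa`, `md`, `ad`, `rd`, `ndi`, `odi`).
#' @param weight,method passed to [tract_mean()].
#' @return a tidy tibble: `subject`, `group`, `age`, `bundle`,
#'   `hemisphere` (`"L"`, `"R"` or `"avg"`), `metric`, `value`,
#'   `n_points`, `n_dropped`.
#' @export
build_cohort_table <- function(subjects, dissections, metrics,
                               weight = "point", method = "trilinear") {
  subjects <- tibble::as_tibble(subjects)
  rows <- purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject[i]
    bnd <- dissections[[i]]
    met <- metrics[[i]]
    purrr::map_dfr(names(bnd), function(bname) {
      if (length(bnd[[bname]]) == 0) {
        message("subject ", sid, ": empty bundle ", bname, "; excluded")
        return(NULL)
      }
      purrr::map_dfr(names(met), function(mname) {
        tm <- tract_mean(met[[mname]], bnd[[bname]], weight = weight,
                         method = method)
        parts <- strsplit(bname, " (?=[LR]$)", perl = TRUE)[[1]]
        tibble::tibble(
          subject = sid, group = subjects$group[i], age = subjects$age[i],
          bundle = parts[1],
          hemisphere = if (length(parts) == 2) parts[2] else "avg",
          metric = mname, value = as.numeric(tm),
          n_points = attr(tm, "n_points"), n_dropped = attr(tm, "n_dropped")
        )
      })
    })
  })
  avg <- rows |>
    dplyr::filter(.data$hemisphere %in% c("L", "R")) |>
    dplyr::group_by(.data$subject, .data$group, .data$age, .data$bundle,
                    .data$metric) |>
    dplyr::filter(dplyr::n_distinct(.data$hemisphere) == 2) |>
    dplyr::summarise(hemisphere = "avg", value = mean(.data$value),
                     n_points = sum(.data$n_points),
                     n_dropped = sum(.data$n_dropped), .groups = "drop")
  dplyr::bind_rows(rows, avg) |>
    dplyr::arrange(.data$subject, .data$bundle, .data$hemisphere,
                   .data$metric)
}

#' Widen a cohort table to one row per subject
#'
#' @param cohort a tidy cohort table from [build_cohort_table()] or
#'   [simulate_cohort_tables()].
#' @param hemisphere which rows to widen (default the L/R-averaged ones).
#' @return tibble with one row per subject and one `bundle.metric` column
#'   per combination.
#' @export
cohort_table_wide <- function(cohort, hemisphere = "avg") {
  cohort |>
    dplyr::filter(.data$hemisphere == !!hemisphere) |>
    dplyr::select("subject", "group", "age", "bundle", "metric", "value") |>
    tidyr::pivot_wider(names_from = c("bundle", "metric"),
                       values_from = "value", names_sep = ".")
}
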