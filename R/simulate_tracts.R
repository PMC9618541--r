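# Synthetic streamline bundles routed through phantom ROI waypoints. These
# stand in for deterministic whole-brain tractography output: coherent
# SLF-like fronto-parietal bundles plus the two contaminant classes the
# exclusion ROIs are designed to remove (mid-sagittal-crossing "callosal"
# streamlines and temporal-projecting "arcuate" streamlines).

#' Simulate one coherent bundle through ROI waypoints
#'
#' Each streamline visits a jittered point near the centroid of every
#' waypoint ROI, in order, connected by densely sampled straight segments
#' with small per-vertex wiggle. Jittered waypoints are clamped to the
#' interior of their ROI box, so every streamline is guaranteed to place at
#' least one vertex inside each waypoint ROI.
#'
#' @param layout a [make_phantom()] layout.
#' @param waypoints character vector of ROI names, visited in order.
#' @param n number of streamlines (>= 1).
#' @param jitter per-streamline waypoint displacement SD in mm; 0 makes all
#'   streamlines identical.
#' @param step vertex spacing along the path in mm.
#' @param seed integer RNG seed.
#' @return a [tractogram()].
#' @export
simulate_bundle <- function(layout, waypoints, n = 100, jitter = 1,
                            step = 1.5, seed = 1L) {
  stopifnot(inherits(layout, "phantom_layout"))
  if (n < 1) stop("n must be >= 1")
  if (length(waypoints) < 2) stop("need >= 2 waypoint ROIs")
  centroids <- lapply(waypoints, roi_centroid, layout = layout)
  boxes <- lapply(waypoints, roi_box_world, layout = layout)
  set.seed(seed)
  streamlines <- lapply(seq_len(n), function(i) {
    targets <- t(vapply(seq_along(waypoints), function(w) {
      p <- centroids[[w]] + stats::rnorm(3, sd = jitter)
      # clamp inside the ROI box (0.4 voxel margin keeps nearest-voxel
      # membership safe at the box faces)
      margin <- 0.4 * min(sqrt(colSums(layout$affine[1:3, 1:3]^2)))
      pmin(pmax(p, boxes[[w]][1, ] + margin), boxes[[w]][2, ] - margin)
    }, numeric(3)))
    pts <- targets[1, , drop = FALSE]
    for (w in seq_len(nrow(targets) - 1)) {
      a <- targets[w, ]; b <- targets[w + 1, ]
      len <- sqrt(sum((b - a)^2))
      nseg <- max(2L, ceiling(len / step))
      tt <- seq(0, 1, length.out = nseg + 1)[-1]
      seg <- cbind(a[1] + tt * (b[1] - a[1]),
                   a[2] + tt * (b[2] - a[2]),
                   a[3] + tt * (b[3] - a[3]))
      # wiggle interior vertices only; waypoint vertices stay exact
      if (nseg > 1) {
        interior <- seq_len(nseg - 1)
        seg[interior, ] <- seg[interior, ] +
          matrix(stats::rnorm(3 * length(interior), sd = 0.1 * jitter),
                 ncol = 3)
      }
      pts <- rbind(pts, seg)
    }
    pts
  })
  tractogram(streamlines)
}

#' Simulate a mixed whole-brain-like tractogram
#'
#' Concatenates several [simulate_bundle()] outputs — target bundles plus
#' contaminants — into one tractogram with a ground-truth provenance table
#' for recovery testing.
#'
#' @param layout a [make_phantom()] layout.
#' @param bundle_mix a data frame (see [default_bundle_mix()]) with columns
#'   `bundle` (name), `waypoints` (list column of ROI name vectors), `n`
#'   (streamline count) and `contaminant` (logical).
#' @param jitter waypoint jitter SD in mm, passed to [simulate_bundle()].
#' @param seed integer RNG seed.
#' @return list with `tractogram` (all streamlines, mix order preserved)
#'   and `provenance`, a tibble with one row per streamline: `index`,
#'   `bundle`, `contaminant`.
#' @export
simulate_tractogram <- function(layout, bundle_mix = default_bundle_mix(),
                                jitter = 1, seed = 1L) {
  bundle_mix <- tibble::as_tibble(bundle_mix)
  if (sum(bundle_mix$n) == 0) stop("bundle mix has zero total streamlines")
  parts <- lapply(seq_len(nrow(bundle_mix)), function(i) {
    simulate_bundle(layout, bundle_mix$waypoints[[i]], n = bundle_mix$n[i],
                    jitter = jitter, seed = seed + i)
  })
  streamlines <- do.call(c, lapply(parts, function(t) t$streamlines))
  provenance <- tibble::tibble(
    index = seq_along(streamlines),
    bundle = rep(bundle_mix$bundle, bundle_mix$n),
    contaminant = rep(bundle_mix$contaminant, bundle_mix$n)
  )
  list(tractogram = tractogram(streamlines), provenance = provenance)
}

#' Default synthetic bundle mix
#'
#' Six SLF-like bundles (I/II/III, both hemispheres) routed through the
#' include ROIs of the chosen protocol, plus two contaminant classes: a
#' callosal bundle crossing the mid-sagittal plane between the parietal
#' ROIs, and left/right arcuate-like bundles projecting from the middle
#' frontal ROI into the temporal lobe.
#'
#' @param protocol `"neonate"` (SLF II routed via the posterior
#'   middle-frontal ROI) or `"adult"` (SLF II routed via the parietal ROI).
#' @param n_per_bundle streamlines per target bundle.
#' @param n_contaminant streamlines per contaminant bundle.
#' @return tibble suitable for [simulate_tractogram()].
#' @export
default_bundle_mix <- function(protocol = c("neonate", "adult"),
                               n_per_bundle = 100, n_contaminant = 60) {
  protocol <- match.arg(protocol)
  rules <- slf_rules(protocol)
  targets <- tibble::tibble(
    bundle = rules$name,
    waypoints = rules$include,
    n = n_per_bundle,
    contaminant = FALSE
  )
  contam <- tibble::tibble(
    bundle = c("callosal", "arcuate_L", "arcuate_R"),
    waypoints = list(c("PaL", "PaR"), c("MFgL", "TeL"), c("MFgR", "TeR")),
    n = n_contaminant,
    contaminant = TRUE
  )
  dplyr::bind_rows(targets, contam)
}
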