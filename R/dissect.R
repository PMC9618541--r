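# Boolean virtual dissection: a streamline belongs to a bundle iff it
# visits every include ("AND") ROI and touches no exclude ("NOT") ROI.
# ROI membership is tested at streamline vertices (optionally supersampled
# so no segment can step over a thin slab such as the mid-sagittal plane)
# with the nearest-voxel convention floor(c + 0.5) on continuous indices.

#' Selection rule tables for the SLF branches
#'
#' Returns the per-protocol boolean ROI recipes: each branch (I/II/III,
#' left/right) is defined by two include ROIs — a parietal (or, for the
#' neonatal SLF II, a posterior middle-frontal) waypoint and a frontal
#' classifier ROI — plus temporal and mid-sagittal exclusion ROIs. The
#' neonate protocol differs from the adult one only in the SLF II include
#' set. The table ships with the package as JSON.
#'
#' @param protocol `"neonate"` or `"adult"`.
#' @param path optional path to an alternative rules JSON file.
#' @return tibble with columns `name` (e.g. `"SLF II L"`), `bundle`,
#'   `hemisphere`, and list columns `include` and `exclude`.
#' @export
slf_rules <- function(protocol = c("neonate", "adult"), path = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(path)) {
    path <- system.file("extdata", "slf_rules.json", package = "slfmature")
  }
  raw <- jsonlite::read_json(path)
  rows <- raw[[protocol]]
  if (is.null(rows)) stop("no '", protocol, "' protocol in rules file")
  out <- tibble::tibble(
    bundle = vapply(rows, `[[`, character(1), "bundle"),
    hemisphere = vapply(rows, `[[`, character(1), "hemisphere"),
    include = lapply(rows, function(r) unlist(r$include)),
    exclude = lapply(rows, function(r) unlist(r$exclude))
  )
  out$name <- paste(out$bundle, out$hemisphere)
  bad <- mapply(function(i, e) length(intersect(i, e)) > 0 || length(i) == 0,
                out$include, out$exclude)
  if (any(bad)) stop("invalid rule(s): empty include or include/exclude overlap")
  out[, c("name", "bundle", "hemisphere", "include", "exclude")]
}

#' Single selection rule
#'
#' @param name bundle name.
#' @param include character vector of ROI labels that must all be visited.
#' @param exclude character vector of ROI labels none of which may be
#'   touched.
#' @return a one-row rule tibble as in [slf_rules()].
#' @export
selection_rule <- function(name, include, exclude = character(0)) {
  if (length(include) == 0) stop("include set must be non-empty")
  if (length(intersect(include, exclude)) > 0) {
    stop("include and exclude sets must be disjoint")
  }
  tibble::tibble(name = name, bundle = name, hemisphere = NA_character_,
                 include = list(include), exclude = list(exclude))
}

supersample_polyline <- function(pts, step) {
  n <- nrow(pts)
  if (n < 2 || !is.finite(step) || step <= 0) return(pts)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  k <- pmax(1L, ceiling(d / step))
  if (all(k == 1L)) return(pts)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    tt <- seq(0, 1, length.out = k[i] + 1)[-(k[i] + 1)]
    out[[i]] <- cbind(pts[i, 1] + tt * (pts[i + 1, 1] - pts[i, 1]),
                      pts[i, 2] + tt * (pts[i + 1, 2] - pts[i, 2]),
                      pts[i, 3] + tt * (pts[i + 1, 3] - pts[i, 3]))
  }
  rbind(do.call(rbind, out), pts[n, , drop = FALSE])
}

# default supersampling step: half the smallest voxel edge
default_step <- function(labels) {
  min(sqrt(colSums(labels$affine[1:3, 1:3]^2))) / 2
}

# integer label ids touched by each streamline (0 = background dropped)
touched_labels <- function(trk, labels, supersample = TRUE) {
  if (length(trk) == 0) return(list())
  step <- if (supersample) default_step(labels) else Inf
  pts <- lapply(trk$streamlines, supersample_polyline, step = step)
  npts <- vapply(pts, nrow, integer(1))
  all_pts <- do.call(rbind, pts)
  vals <- lookup_voxels(labels, all_pts)
  id <- rep(seq_along(pts), npts)
  keep <- vals != 0
  unname(lapply(split(vals[keep], factor(id[keep], levels = seq_along(pts))),
                unique))
}

#' Test whether a streamline intersects an ROI
#'
#' True iff any tested point of the streamline maps to a voxel carrying
#' `label`. Tested points are the vertices, plus (if `supersample`) points
#' interpolated along each segment so consecutive tests are at most half
#' the smallest voxel edge apart — without this, a long segment can step
#' straight over a one-voxel-thick slab. Points outside the grid are
#' simply outside the ROI.
#'
#' @param streamline n x 3 matrix of world-mm vertices.
#' @param labels integer label [metric_volume()].
#' @param label ROI label id (integer) or name resolvable via
#'   `attr(labels, "labels")`.
#' @param supersample logical; default TRUE.
#' @return logical scalar.
#' @export
streamline_in_roi <- function(streamline, labels, label, supersample = TRUE) {
  step <- if (supersample) default_step(labels) else Inf
  pts <- supersample_polyline(rbind_points(streamline), step)
  any(lookup_voxels(labels, pts) == label)
}

#' Select streamlines by a boolean ROI rule
#'
#' Keeps a streamline iff it visits every include ROI (at least one tested
#' point inside each, in any order) and touches no exclude ROI. Input
#' order is preserved; kept and rejected sets partition the input.
#'
#' @param trk a [tractogram()].
#' @param rule a one-row rule (from [slf_rules()] or [selection_rule()]).
#' @param layout a [make_phantom()] layout, or a list with elements
#'   `volume` (label [metric_volume()]) and `labels` (name -> id map).
#' @param supersample logical; see [streamline_in_roi()].
#' @return list with `tractogram` (kept streamlines) and `kept` (indices
#'   into the input).
#' @export
select_streamlines <- function(trk, rule, layout, supersample = TRUE) {
  touched <- touched_labels(trk, layout$volume, supersample)
  kept <- which(rule_keeps(rule, touched, layout$labels))
  list(tractogram = tractogram(trk$streamlines[kept], trk$header),
       kept = kept)
}

rule_keeps <- function(rule, touched, label_map) {
  inc <- roi_ids(rule$include[[1]], label_map)
  exc <- roi_ids(rule$exclude[[1]], label_map)
  vapply(touched, function(tl) {
    all(inc %in% tl) && !any(exc %in% tl)
  }, logical(1))
}

roi_ids <- function(names, label_map) {
  ids <- label_map[names]
  if (any(is.na(ids))) {
    stop("unknown ROI label(s): ",
         paste(names[is.na(ids)], collapse = ", "))
  }
  unname(ids)
}

#' Dissect the six SLF branches from a whole-brain tractogram
#'
#' Applies the six selection rules of the chosen protocol. A streamline
#' satisfying two rules is reported in both bundles (with a warning);
#' optionally, streamlines ambiguous between SLF II and SLF III of the
#' same hemisphere are assigned uniquely by mean vertex height (more
#' dorsal streamlines to SLF II).
#'
#' @param trk a [tractogram()].
#' @param layout a [make_phantom()] layout (or equivalent label volume +
#'   label map, see [select_streamlines()]).
#' @param protocol `"neonate"` or `"adult"`, or a rules tibble from
#'   [slf_rules()].
#' @param supersample logical; see [streamline_in_roi()].
#' @param resolve_overlap logical; default FALSE (streamlines may appear
#'   in two bundles).
#' @return named list of six [tractogram()]s; attribute `"report"` holds a
#'   tibble with per-rule kept counts and indices.
#' @export
dissect_slf <- function(trk, layout, protocol = "neonate",
                        supersample = TRUE, resolve_overlap = FALSE) {
  rules <- if (is.character(protocol)) slf_rules(protocol) else protocol
  touched <- touched_labels(trk, layout$volume, supersample)
  kept_idx <- lapply(seq_len(nrow(rules)), function(i) {
    which(rule_keeps(rules[i, ], touched, layout$labels))
  })
  names(kept_idx) <- rules$name

  dup <- table(unlist(kept_idx))
  if (any(dup > 1)) {
    amb <- as.integer(names(dup[dup > 1]))
    if (resolve_overlap) {
      meanz <- vapply(trk$streamlines, function(s) mean(s[, 3]), numeric(1))
      for (h in unique(rules$hemisphere)) {
        i2 <- which(rules$bundle == "SLF II" & rules$hemisphere == h)
        i3 <- which(rules$bundle == "SLF III" & rules$hemisphere == h)
        if (length(i2) != 1 || length(i3) != 1) next
        both <- intersect(kept_idx[[i2]], kept_idx[[i3]])
        if (length(both) == 0) next
        zsplit <- stats::median(meanz[unique(c(kept_idx[[i2]],
                                               kept_idx[[i3]]))])
        to2 <- both[meanz[both] >= zsplit]
        kept_idx[[i3]] <- setdiff(kept_idx[[i3]], to2)
        kept_idx[[i2]] <- setdiff(kept_idx[[i2]], setdiff(both, to2))
      }
    } else {
      warning(length(amb), " streamline(s) satisfy more than one rule; ",
              "reported in every matching bundle")
    }
  }

  bundles <- lapply(kept_idx, function(idx) {
    tractogram(trk$streamlines[idx], trk$header)
  })
  report <- tibble::tibble(
    name = rules$name,
    n_kept = vapply(kept_idx, length, integer(1)),
    kept = kept_idx
  )
  attr(bundles, "report") <- report
  bundles
}
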