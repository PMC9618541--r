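#' Scalar volume with a voxel-to-world affine
#'
#' A `metric_volume` couples a 3-D (or 4-D, for diffusion-weighted series)
#' numeric array with a 4x4 affine mapping 0-based continuous voxel indices
#' to world coordinates in millimetres. It is the in-memory form of every
#' NIfTI image the pipeline touches: per-metric maps (FA, MD, AD, RD, NDI,
#' ODI), integer ROI label volumes, and 4-D DWI series.
#'
#' Diffusivity maps (MD/AD/RD) are in mm^2/s; FA, NDI and ODI are
#' dimensionless. ROI label volumes must contain only non-negative integers.
#'
#' @param data numeric array, 3-D or 4-D, every axis of length >= 1.
#' @param affine 4x4 invertible matrix; voxel index (i,j,k,1) maps to world
#'   (x,y,z,1). Indices are 0-based, matching the NIfTI convention.
#' @return an object of class `metric_volume`.
#' @export
metric_volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (!length(dim(data)) %in% c(3L, 4L)) {
    stop("`data` must be a 3-D or 4-D array, got ", length(dim(data)), " dims")
  }
  if (any(dim(data) < 1L)) stop("every axis of `data` must have length >= 1")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("`affine` must be 4x4")
  det_a <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop("`affine` is not invertible (|det| = ", format(abs(det_a)), ")")
  }
  structure(list(data = data, affine = affine), class = "metric_volume")
}

#' @export
print.metric_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<metric_volume> ", paste(d, collapse = " x "), "\n", sep = "")
  cat("  voxel size (mm): ",
      paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 4), collapse = " x "),
      "\n", sep = "")
  rng <- range(x$data)
  cat("  data range: [", format(rng[1]), ", ", format(rng[2]), "]\n", sep = "")
  invisible(x)
}

#' Convert between voxel indices and world millimetres
#'
#' Indices are 0-based and continuous: voxel `i` is centred at index `i` and
#' spans `[i - 0.5, i + 0.5)` in index space.
#'
#' @param volume a [metric_volume()].
#' @param points n x 3 matrix of points (voxel indices or world mm).
#' @return n x 3 matrix of transformed points.
#' @export
voxel_to_world <- function(volume, points) {
  points <- rbind_points(points)
  t(volume$affine[1:3, 1:3] %*% t(points) + volume$affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, points) {
  points <- rbind_points(points)
  inv <- solve(volume$affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be n x 3")
  points
}

#' Nearest-voxel lookup of label values at world points
#'
#' Maps world-mm points to voxels by the nearest-voxel convention
#' `floor(c + 0.5)` on the continuous 0-based index `c`, and returns the
#' stored value there. Points outside the grid return `outside`.
#'
#' @param volume a 3-D [metric_volume()].
#' @param points n x 3 matrix of world-mm points.
#' @param outside value returned for points outside the grid (default 0,
#'   the background label).
#' @return numeric vector of length n.
#' @export
lookup_voxels <- function(volume, points, outside = 0) {
  points <- rbind_points(points)
  idx <- floor(world_to_voxel(volume, points) + 0.5)
  d <- dim(volume$data)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- rep(outside, nrow(points))
  if (any(ok)) {
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    out[ok] <- volume$data[lin]
  }
  out
}
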