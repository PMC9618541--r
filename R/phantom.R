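# Schematic phantom standing in for the hand-drawn ROI protocol: coronal
# frontal ROIs (superior/middle/precentral gyrus) anterior to the AC plane,
# coronal parietal ROIs posterior to the PC plane, the posterior
# middle-frontal ROI strictly between AC and PC, axial temporal exclusion
# slabs, and a 1-voxel mid-sagittal exclusion plane. Boxes, not anatomy.

#' The 13 phantom ROI names
#'
#' Label order of the phantom ROI volume: frontal (superior, middle,
#' precentral), parietal and temporal boxes left/right, the mid-sagittal
#' plane, and the posterior middle-frontal boxes.
#' @export
PHANTOM_ROI_NAMES <- c("SFgL", "SFgR", "MFgL", "MFgR", "PrgL", "PrgR",
                       "PaL", "PaR", "TeL", "TeR", "Midsag",
                       "MFgL-P", "MFgR-P")

#' Build the phantom ROI layout
#'
#' Constructs an axis-aligned box/slab layout of the 13 ROI labels used to
#' dissect the SLF branches: left/right superior, middle and precentral
#' frontal gyrus boxes (anterior to the anterior-commissure plane),
#' left/right parietal boxes (posterior to the posterior-commissure plane),
#' posterior middle-frontal boxes strictly between the two commissure
#' planes, left/right temporal exclusion slabs, and a one-voxel-thick
#' mid-sagittal exclusion plane. Left and right ROIs are exact mirror
#' images across the mid-sagittal plane.
#'
#' Axes follow the usual convention: x left-right, y posterior-anterior,
#' z inferior-superior.
#'
#' @param shape integer grid dimensions, each >= 40 voxels.
#' @param voxel_mm isotropic voxel edge in millimetres.
#' @return an object of class `phantom_layout`: list with `shape`,
#'   `affine`, `rois` (named list of 0-based inclusive voxel index boxes
#'   `c(x0, x1, y0, y1, z0, z1)`), commissure plane indices `ac`/`pc`,
#'   the label lookup `labels` (name -> integer id) and `volume`, the
#'   integer label [metric_volume()].
#' @export
make_phantom <- function(shape = c(48L, 48L, 48L), voxel_mm = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 40L)) {
    stop("phantom grid must be 3-D with >= 40 voxels per axis")
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # world origin at grid centre
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2

  midx <- nx %/% 2L                       # mirror plane x -> nx - x
  y_ac <- round(0.62 * ny)                # anterior commissure plane
  y_pc <- round(0.33 * ny)                # posterior commissure plane
  sc <- function(f, n) as.integer(round(f * n / 48))  # scale 48-grid template

  xl <- c(sc(4, nx), sc(20, nx))          # left hemisphere lateral extent
  y_front <- c(y_ac + 2L, min(y_ac + 2L + sc(3, ny), ny - 2L))
  y_par <- c(max(y_pc - 6L, 1L), y_pc - 3L)
  y_mfgp <- c(y_pc + 4L, y_ac - 4L)

  box <- function(x, y, z) c(x[1], x[2], y[1], y[2], z[1], z[2])
  rois_left <- list(
    SFgL = box(xl, y_front, c(sc(32, nz), sc(40, nz))),
    MFgL = box(xl, y_front, c(sc(22, nz), sc(30, nz))),
    PrgL = box(xl, y_front, c(sc(12, nz), sc(20, nz))),
    PaL  = box(xl, y_par, c(sc(10, nz), sc(42, nz))),
    TeL  = box(xl, c(sc(6, ny), sc(32, ny)), c(sc(2, nz), sc(6, nz))),
    `MFgL-P` = box(xl, y_mfgp, c(sc(22, nz), sc(30, nz)))
  )
  mirror <- function(b) c(2L * midx - b[2], 2L * midx - b[1], b[3:6])
  rois <- c(rois_left, stats::setNames(lapply(rois_left, mirror),
                                       sub("L", "R", names(rois_left))))
  rois$Midsag <- c(midx, midx, 0L, ny - 1L, 0L, nz - 1L)
  rois <- rois[PHANTOM_ROI_NAMES]

  for (b in rois) {
    if (any(b[c(1, 3, 5)] < 0) || b[2] >= nx || b[4] >= ny || b[6] >= nz) {
      stop("phantom grid too small to place all ROIs")
    }
  }

  labels <- stats::setNames(seq_along(PHANTOM_ROI_NAMES), PHANTOM_ROI_NAMES)
  lab <- array(0L, dim = shape)
  for (nm in PHANTOM_ROI_NAMES) {
    b <- rois[[nm]]
    sub <- lab[(b[1] + 1):(b[2] + 1), (b[3] + 1):(b[4] + 1),
               (b[5] + 1):(b[6] + 1)]
    if (any(sub != 0L)) stop("phantom ROIs overlap at ", nm)
    lab[(b[1] + 1):(b[2] + 1), (b[3] + 1):(b[4] + 1),
        (b[5] + 1):(b[6] + 1)] <- labels[[nm]]
  }

  structure(list(shape = shape, affine = affine, rois = rois,
                 ac = y_ac, pc = y_pc, labels = labels,
                 volume = metric_volume(lab, affine)),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("<phantom_layout> ", paste(x$shape, collapse = " x "),
      " voxels, ", length(x$rois), " ROIs\n", sep = "")
  invisible(x)
}

#' ROI centroid in world millimetres
#'
#' @param layout a [make_phantom()] layout.
#' @param name ROI name (e.g. `"PaL"`).
#' @return length-3 world-mm coordinate of the ROI box centre.
#' @export
roi_centroid <- function(layout, name) {
  b <- layout$rois[[name]]
  if (is.null(b)) stop("unknown ROI name: ", name)
  idx <- c(mean(b[1:2]), mean(b[3:4]), mean(b[5:6]))
  drop(voxel_to_world(layout$volume, matrix(idx, 1)))
}

roi_box_world <- function(layout, name) {
  b <- layout$rois[[name]]
  if (is.null(b)) stop("unknown ROI name: ", name)
  lo <- drop(voxel_to_world(layout$volume, matrix(b[c(1, 3, 5)], 1)))
  hi <- drop(voxel_to_world(layout$volume, matrix(b[c(2, 4, 6)], 1)))
  rbind(pmin(lo, hi), pmax(lo, hi))
}
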