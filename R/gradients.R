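#' Multi-shell gradient scheme
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions defining a
#' diffusion acquisition, e.g. the neonatal four-shell scheme with
#' b = 0/400/1000/2600 s/mm^2 and 20/64/88/128 directions.
#'
#' Directions of diffusion-weighted volumes are normalised to unit length;
#' a zero direction with b > 0 is a validation error. b = 0 volumes may
#' carry a zero direction.
#'
#' @param bvals numeric vector of b-values, >= 0.
#' @param bvecs n x 3 matrix of gradient directions.
#' @return an object of class `gradient_scheme` — a tibble with columns
#'   `b`, `gx`, `gy`, `gz` and `shell` (nominal shell b-value, grouped with
#'   a +/- 50 s/mm^2 tolerance).
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- rbind_points(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") differ in length")
  }
  if (any(bvals < 0)) stop("b-values must be >= 0")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > B_SHELL_TOL
  if (any(dw & nrm < 1e-8)) {
    stop("zero gradient direction with non-zero b-value at volume(s) ",
         paste(which(dw & nrm < 1e-8), collapse = ", "))
  }
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  bvecs[!dw, ] <- 0
  out <- tibble::tibble(b = bvals, gx = bvecs[, 1], gy = bvecs[, 2],
                        gz = bvecs[, 3])
  out$shell <- group_shells(bvals)
  class(out) <- c("gradient_scheme", class(out))
  out
}

B_SHELL_TOL <- 50  # s/mm^2; real schemes jitter nominal b-values

# assign each b-value to a shell: cluster within +/- B_SHELL_TOL of the
# running shell mean, label by the rounded mean. Permutation-invariant.
group_shells <- function(bvals) {
  ord <- order(bvals)
  b <- bvals[ord]
  shell_id <- integer(length(b))
  centre <- -Inf; id <- 0L; members <- numeric(0)
  for (i in seq_along(b)) {
    if (b[i] - centre > B_SHELL_TOL) {
      id <- id + 1L
      members <- b[i]
    } else {
      members <- c(members, b[i])
    }
    centre <- mean(members)
    shell_id[i] <- id
  }
  centres <- round(tapply(b, shell_id, mean))
  out <- numeric(length(bvals))
  out[ord] <- centres[shell_id]
  out
}

#' Read gradient tables
#'
#' Reads either the FSL dialect (two files: one row of b-values, three rows
#' of direction components) or the MRtrix dialect (one four-column file:
#' x y z b). The two dialects of the same table produce identical schemes.
#'
#' @param path for `dialect = "mrtrix"`, the four-column gradient file; for
#'   `dialect = "fsl"`, the bval file.
#' @param bvec_path for `dialect = "fsl"`, the bvec file.
#' @param dialect `"fsl"` or `"mrtrix"`.
#' @return a [gradient_scheme()].
#' @export
read_gradients <- function(path, bvec_path = NULL,
                           dialect = c("mrtrix", "fsl")) {
  dialect <- match.arg(dialect)
  if (dialect == "mrtrix") {
    tab <- as.matrix(utils::read.table(path, comment.char = "#"))
    if (ncol(tab) != 4) stop("MRtrix gradient table must have 4 columns")
    gradient_scheme(tab[, 4], tab[, 1:3])
  } else {
    if (is.null(bvec_path)) stop("FSL dialect needs both bval and bvec files")
    bvals <- scan(path, quiet = TRUE)
    bvecs <- as.matrix(utils::read.table(bvec_path))
    if (nrow(bvecs) != 3) stop("FSL bvec file must have 3 rows")
    gradient_scheme(bvals, t(bvecs))
  }
}

#' Write a gradient scheme
#'
#' @param scheme a [gradient_scheme()].
#' @param path output path (MRtrix) or bval path (FSL).
#' @param bvec_path bvec path for the FSL dialect.
#' @inheritParams read_gradients
#' @return `path`, invisibly.
#' @export
write_gradients <- function(scheme, path, bvec_path = NULL,
                            dialect = c("mrtrix", "fsl")) {
  dialect <- match.arg(dialect)
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  if (dialect == "mrtrix") {
    utils::write.table(cbind(g, scheme$b), path, row.names = FALSE,
                       col.names = FALSE)
  } else {
    if (is.null(bvec_path)) stop("FSL dialect needs both bval and bvec paths")
    writeLines(paste(scheme$b, collapse = " "), path)
    utils::write.table(t(g), bvec_path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Shell summary of a gradient scheme
#'
#' @param scheme a [gradient_scheme()].
#' @return tibble with one row per shell: nominal `shell` b-value and the
#'   number of volumes `n`.
#' @export
shell_table <- function(scheme) {
  dplyr::count(tibble::as_tibble(scheme), .data$shell, name = "n")
}

#' Extract a sub-scheme by shell
#'
#' Keeps only the volumes whose shell matches one of `keep_b` (within the
#' +/- 50 s/mm^2 shell tolerance), preserving acquisition order — e.g. the
#' b = 0 and b = 1000 sub-scheme used for tensor fitting.
#'
#' @param scheme a [gradient_scheme()].
#' @param keep_b numeric vector of nominal shell b-values to keep.
#' @return list with `scheme` (the sub-scheme) and `index` (positions of
#'   the kept volumes in the input).
#' @export
extract_subscheme <- function(scheme, keep_b) {
  shells <- unique(scheme$shell)
  matched <- vapply(keep_b, function(b) {
    hit <- which(abs(shells - b) <= B_SHELL_TOL)
    if (length(hit) == 0) {
      stop("requested shell b=", b, " not present (available: ",
           paste(shells, collapse = ", "), ")")
    }
    shells[hit[1]]
  }, numeric(1))
  idx <- which(scheme$shell %in% matched)
  list(scheme = gradient_scheme(scheme$b[idx],
                                as.matrix(scheme[idx, c("gx", "gy", "gz")])),
       index = idx)
}

#' The neonatal four-shell acquisition scheme
#'
#' Builds a synthetic gradient scheme mirroring the neonatal multi-shell
#' protocol: shells b = 0, 400, 1000, 2600 s/mm^2 with 20, 64, 88 and 128
#' directions (300 volumes). Directions are spread quasi-uniformly on the
#' sphere by a Fibonacci lattice.
#'
#' @param seed integer seed controlling the (deterministic) lattice
#'   rotation per shell.
#' @return a [gradient_scheme()].
#' @export
dhcp_scheme <- function(seed = 1L) {
  shells <- c(0, 400, 1000, 2600)
  ndir <- c(20, 64, 88, 128)
  bvals <- rep(shells, ndir)
  set.seed(seed)
  bvecs <- do.call(rbind, lapply(seq_along(shells), function(i) {
    if (shells[i] == 0) return(matrix(0, ndir[i], 3))
    fibonacci_sphere(ndir[i], phase = stats::runif(1, 0, 2 * pi))
  }))
  gradient_scheme(bvals, bvecs)
}

fibonacci_sphere <- function(n, phase = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * i + phase
  cbind(r * cos(th), r * sin(th), z)
}
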