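# Log-linear diffusion tensor fit: ln S = ln S0 - b g' D g, solved by OLS
# followed by one weighted refit with predicted-signal-squared weights
# (the standard WLS scheme; stable and reproducible).

dti_design <- function(scheme) {
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  b <- scheme$b
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor to one voxel's signals
#'
#' Weighted least-squares solution of the log-linear tensor model with one
#' WLS iteration from an OLS start (weights = squared predicted signals).
#' Non-positive signal samples are dropped (and counted); the fit needs at
#' least 7 usable volumes including one b = 0.
#'
#' @param signals numeric vector, one signal per volume.
#' @param scheme a [gradient_scheme()] with matching length.
#' @param wls logical; FALSE gives the plain OLS solution.
#' @return an object of class `tensor_fit`: the 3x3 tensor `D` (mm^2/s),
#'   `s0`, eigenvalues `lambda` (sorted descending), eigenvectors `vectors`
#'   (columns, matching order), `n_dropped` non-positive samples and
#'   `n_negative_ev` negative eigenvalues.
#' @export
fit_dti <- function(signals, scheme, wls = TRUE) {
  if (length(signals) != nrow(scheme)) {
    stop("signals (", length(signals), ") and scheme (", nrow(scheme),
         ") differ in length")
  }
  ok <- is.finite(signals) & signals > 0
  n_dropped <- sum(!ok)
  if (sum(ok) < 7) stop("need >= 7 positive signals to fit a tensor")
  if (!any(scheme$b[ok] <= B_SHELL_TOL)) stop("need >= 1 usable b=0 volume")
  X <- dti_design(scheme)[ok, , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < 7) stop("rank-deficient gradient design (rank ", qx$rank, ")")
  y <- log(signals[ok])
  beta <- qr.coef(qx, y)
  if (wls) {
    w <- exp(2 * as.numeric(X %*% beta))   # predicted-signal^2 weights
    sw <- sqrt(w)
    beta <- qr.coef(qr(X * sw), y * sw)
  }
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  structure(list(D = D, s0 = exp(beta[1]),
                 lambda = e$values, vectors = e$vectors,
                 n_dropped = n_dropped,
                 n_negative_ev = sum(e$values < 0)),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat("<tensor_fit> eigenvalues (mm^2/s): ",
      paste(signif(x$lambda, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scalar metrics of a tensor fit
#'
#' Standard eigenvalue formulas: `MD = (l1+l2+l3)/3`, `AD = l1`,
#' `RD = (l2+l3)/2`, `FA = sqrt(3/2) * ||l - MD|| / ||l||` (0 when all
#' eigenvalues vanish). Negative eigenvalues are clamped to 0 for the
#' metric computation (keeping FA in `[0, 1]`) and counted.
#'
#' @param fit a `tensor_fit`, or a numeric vector of 3 eigenvalues.
#' @return one-row tibble: `fa`, `md`, `ad`, `rd`, `n_negative_ev`.
#' @export
tensor_metrics <- function(fit) {
  lambda <- if (inherits(fit, "tensor_fit")) fit$lambda else sort(fit, TRUE)
  n_neg <- sum(lambda < 0)
  l <- pmax(lambda, 0)
  md <- mean(l)
  nrm <- sqrt(sum(l^2))
  fa <- if (nrm == 0) 0 else
    min(1, sqrt(3 / 2) * sqrt(sum((l - md)^2)) / nrm)
  tibble::tibble(fa = fa, md = md, ad = l[1], rd = (l[2] + l[3]) / 2,
                 n_negative_ev = n_neg)
}

#' Voxelwise tensor metrics for a 4-D DWI volume
#'
#' Fits [fit_dti()] in every voxel of a 4-D series (optionally restricted
#' to a mask) and returns one 3-D map per metric plus the principal
#' eigenvector field (used as the mean neurite direction by
#' [fit_noddi()]). Voxels where the fit fails or that are outside the
#' mask get NA metrics.
#'
#' @param dwi 4-D [metric_volume()] of signals.
#' @param scheme matching [gradient_scheme()].
#' @param mask optional 3-D logical/0-1 array.
#' @return list of 3-D [metric_volume()]s `fa`, `md`, `ad`, `rd`, plus
#'   `v1`, a 4-D volume holding the principal eigenvector.
#' @export
fit_dti_volume <- function(dwi, scheme, mask = NULL) {
  d <- dim(dwi$data)
  if (length(d) != 4) stop("dwi must be a 4-D volume")
  shape <- d[1:3]
  nvox <- prod(shape)
  sig <- matrix(dwi$data, nvox, d[4])
  use <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  maps <- matrix(NA_real_, nvox, 4)
  v1 <- matrix(NA_real_, nvox, 3)
  for (v in which(use)) {
    fit <- tryCatch(fit_dti(sig[v, ], scheme), error = function(e) NULL)
    if (is.null(fit)) next
    m <- tensor_metrics(fit)
    maps[v, ] <- c(m$fa, m$md, m$ad, m$rd)
    v1[v, ] <- fit$vectors[, 1]
  }
  out <- lapply(1:4, function(j) {
    metric_volume(array(maps[, j], shape), dwi$affine)
  })
  names(out) <- c("fa", "md", "ad", "rd")
  out$v1 <- metric_volume(array(v1, c(shape, 3)), dwi$affine)
  out
}
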