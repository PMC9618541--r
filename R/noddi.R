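# Simplified NODDI fit: coarse grid search over (ndi, odi, f_iso) against
# the three-compartment forward model, followed by bounded local
# refinement. The mean neurite direction is taken from the DTI principal
# eigenvector, and the diffusivities are fixed at the conventional values,
# so only the three fractions/dispersion parameters are estimated.

#' Fit the simplified NODDI model to one voxel's signals
#'
#' Minimises the sum-of-squares misfit between the normalised measured
#' signals and [noddi_signal()] over `(ndi, odi, f_iso)`. A grid search
#' (default step 0.05) locates the basin; bounded Nelder-Mead-style
#' refinement (via `optim` L-BFGS-B, tolerance 1e-4) polishes the optimum.
#' Needs a multi-shell scheme (>= 2 non-zero shells) — the model is
#' degenerate on a single shell. When the fitted free-water fraction
#' exceeds 0.95 the tissue parameters are unidentifiable and flagged.
#'
#' @param signals numeric vector of signals, one per volume (absolute
#'   scale; normalised internally by the mean b = 0 signal).
#' @param scheme matching [gradient_scheme()].
#' @param mu unit mean neurite direction (e.g. the DTI principal
#'   eigenvector); estimated from a tensor fit when `NULL`.
#' @param grid_step grid resolution for the global search.
#' @param refine logical; run the bounded local refinement.
#' @param d_par,d_iso fixed model diffusivities (mm^2/s).
#' @return an object of class `noddi_fit`: `ndi`, `odi`, `f_iso`,
#'   `rss` (residual sum of squares), `mu` and `unidentifiable`.
#' @export
fit_noddi <- function(signals, scheme, mu = NULL, grid_step = 0.05,
                      refine = TRUE, d_par = D_PAR_DEFAULT,
                      d_iso = D_ISO_DEFAULT) {
  if (length(signals) != nrow(scheme)) {
    stop("signals and scheme differ in length")
  }
  shells <- setdiff(unique(scheme$shell), 0)
  if (length(shells) < 2) {
    stop("NODDI needs >= 2 non-zero shells (got ", length(shells), ")")
  }
  b0 <- scheme$b <= B_SHELL_TOL
  if (!any(b0)) stop("scheme needs >= 1 b=0 volume")
  s0 <- mean(signals[b0])
  if (!is.finite(s0) || s0 <= 0) stop("non-positive b=0 signal")
  y <- signals / s0
  if (is.null(mu)) {
    mu <- fit_dti(signals, scheme)$vectors[, 1]
  }
  mu <- mu / sqrt(sum(mu^2))
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  cosang <- as.numeric(g %*% mu)
  b <- scheme$b

  sse <- function(p) {
    pred <- noddi_signal(p[1], p[2], p[3], b, cosang,
                         d_par = d_par, d_iso = d_iso)
    sum((pred - y)^2)
  }

  ndi_grid <- seq(0, 1, by = grid_step)
  odi_grid <- seq(grid_step, 1, by = grid_step)
  f_grid <- seq(0, 1, by = grid_step)
  e_iso <- exp(-b * d_iso)
  best <- NULL
  for (odi in odi_grid) {
    kappa <- odi_to_kappa(odi)
    a_i <- watson_stick_attenuation(b * d_par, kappa, cosang)
    tau <- watson_tau(kappa)
    for (ndi in ndi_grid) {
      d_perp <- d_par * (1 - ndi)
      q <- (d_par - d_perp) *
        (tau * cosang^2 + (1 - tau) * (1 - cosang^2) / 2) + d_perp
      tissue <- ndi * a_i + (1 - ndi) * exp(-b * q)
      # rss over the f_iso grid in one matrix op
      pred <- outer(tissue, 1 - f_grid) + outer(e_iso, f_grid)
      rss <- colSums((pred - y)^2)
      j <- which.min(rss)
      if (is.null(best) || rss[j] < best$rss) {
        best <- list(p = c(ndi, odi, f_grid[j]), rss = rss[j])
      }
    }
  }

  p <- best$p; rss <- best$rss
  if (refine) {
    opt <- stats::optim(p, sse, method = "L-BFGS-B",
                        lower = c(0, 1e-2, 0), upper = c(1, 1, 1),
                        control = list(factr = 1e4, maxit = 200))
    if (opt$value <= rss) {
      p <- opt$par; rss <- opt$value
    }
  }
  structure(list(ndi = p[1], odi = p[2], f_iso = p[3], rss = rss,
                 mu = mu, unidentifiable = p[3] >= 0.95),
            class = "noddi_fit")
}

#' @export
print.noddi_fit <- function(x, ...) {
  cat(sprintf("<noddi_fit> ndi = %.3f, odi = %.3f, f_iso = %.3f (rss %.2e)%s\n",
              x$ndi, x$odi, x$f_iso, x$rss,
              if (x$unidentifiable) " [free-water dominated]" else ""))
  invisible(x)
}

#' Voxelwise NODDI maps for a 4-D DWI volume
#'
#' Runs [fit_noddi()] in every (masked) voxel, taking the mean neurite
#' direction per voxel from the DTI principal eigenvector field.
#'
#' @inheritParams fit_dti_volume
#' @param v1 optional 4-D principal-eigenvector volume from
#'   [fit_dti_volume()]; computed when `NULL`.
#' @param ... passed to [fit_noddi()].
#' @return list of 3-D [metric_volume()]s `ndi`, `odi`, `f_iso`.
#' @export
fit_noddi_volume <- function(dwi, scheme, mask = NULL, v1 = NULL, ...) {
  d <- dim(dwi$data)
  if (length(d) != 4) stop("dwi must be a 4-D volume")
  shape <- d[1:3]
  nvox <- prod(shape)
  sig <- matrix(dwi$data, nvox, d[4])
  use <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  if (is.null(v1)) v1 <- fit_dti_volume(dwi, scheme, mask)$v1
  v1m <- matrix(v1$data, nvox, 3)
  maps <- matrix(NA_real_, nvox, 3)
  for (v in which(use)) {
    mu <- v1m[v, ]
    if (!all(is.finite(mu))) next
    fit <- tryCatch(fit_noddi(sig[v, ], scheme, mu = mu, ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    maps[v, ] <- c(fit$ndi, fit$odi, fit$f_iso)
  }
  out <- lapply(1:3, function(j) {
    metric_volume(array(maps[, j], shape), dwi$affine)
  })
  stats::setNames(out, c("ndi", "odi", "f_iso"))
}
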