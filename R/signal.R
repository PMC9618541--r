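# Three-compartment diffusion signal model: an intra-neurite compartment of
# Watson-dispersed sticks (zero perpendicular diffusivity), an extra-neurite
# zeppelin whose dispersion and tortuosity are tied to the stick compartment
# (d_perp = d_par * (1 - ndi)), and isotropic free water. Signals are
# normalised (S/S0). The Watson sphere integrals reduce, after analytic
# azimuthal integration via the Bessel function I0, to a 1-D polar integral
# evaluated by Gauss-Legendre quadrature; everything is kept in log space so
# large Watson concentrations cannot overflow.

D_PAR_DEFAULT <- 1.7e-3   # intrinsic parallel diffusivity, mm^2/s
D_ISO_DEFAULT <- 3.0e-3   # free-water diffusivity, mm^2/s

#' Convert between orientation dispersion index and Watson concentration
#'
#' `odi = (2/pi) * atan(1/kappa)`; odi near 0 means tightly aligned
#' neurites (large kappa), odi = 1 means fully dispersed (kappa = 0).
#'
#' @param odi orientation dispersion index in (0, 1].
#' @param kappa Watson concentration parameter, >= 0.
#' @return the converted parameter.
#' @export
odi_to_kappa <- function(odi) {
  stopifnot(all(odi > 0), all(odi <= 1))
  1 / tan(pi / 2 * odi)
}

#' @rdname odi_to_kappa
#' @export
kappa_to_odi <- function(kappa) {
  stopifnot(all(kappa >= 0))
  2 / pi * atan2(1, kappa)
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

.quad_env <- new.env(parent = emptyenv())
gl64 <- function() {
  if (is.null(.quad_env$gl)) .quad_env$gl <- gauss_legendre(64)
  .quad_env$gl
}

# log of  N(b1, b2) = int_{S^2} exp(b1*n1^2 + b2*n2^2) dOmega,
# via  N = 2*pi * int_{-1}^{1} exp((1-u^2)*s) I0((1-u^2)*d) du,
# s = (b1+b2)/2, d = (b1-b2)/2. Vectorised over (b1, b2) pairs.
log_sphere_exp_quad <- function(b1, b2) {
  gl <- gl64()
  u2 <- gl$nodes^2                       # 64 nodes
  s <- (b1 + b2) / 2
  d <- (b1 - b2) / 2
  # exponent matrix: nodes x pairs
  f <- outer(1 - u2, s)                  # (1-u^2) * s
  x <- outer(1 - u2, d)                  # argument of I0
  lg <- f + abs(x) + log(besselI(abs(x), 0, expon.scaled = TRUE))
  m <- apply(lg, 2, max)
  log(colSums(gl$weights * exp(sweep(lg, 2, m)))) + m + log(2 * pi)
}

# E[(n . mu)^2] under Watson(kappa): 1-D quadrature on the polar cosine
watson_tau <- function(kappa) {
  gl <- gl64()
  t2 <- gl$nodes^2
  vapply(kappa, function(k) {
    w <- gl$weights * exp(k * (t2 - 1))  # shift by -k to avoid overflow
    sum(w * t2) / sum(w)
  }, numeric(1))
}

#' Intra-neurite (Watson-dispersed stick) signal attenuation
#'
#' Attenuation `E[exp(-b d_par (g . n)^2)]` under a Watson orientation
#' distribution with mean direction `mu` and concentration `kappa`,
#' evaluated per volume. `cosang` is the cosine of the angle between the
#' gradient direction and `mu`.
#'
#' @param bd product `b * d_par` per volume (dimensionless).
#' @param kappa Watson concentration (scalar).
#' @param cosang cosine of gradient/mean-direction angle per volume.
#' @return attenuation in (0, 1], one value per volume.
#' @export
watson_stick_attenuation <- function(bd, kappa, cosang) {
  a <- bd
  c2 <- cosang^2
  s2 <- pmax(1 - c2, 0)
  tr <- kappa - a
  disc <- sqrt(tr^2 + 4 * a * kappa * s2)
  b1 <- (tr + disc) / 2
  b2 <- (tr - disc) / 2
  exp(log_sphere_exp_quad(b1, b2) - log_sphere_exp_quad(kappa, 0))
}

#' Normalised three-compartment diffusion signal
#'
#' Forward model `S/S0 = (1 - f_iso) * [ndi * A_intra + (1 - ndi) *
#' A_extra] + f_iso * exp(-b d_iso)`, with `A_intra` the Watson-dispersed
#' stick and `A_extra` a zeppelin whose mean tensor follows the same
#' Watson distribution and whose perpendicular diffusivity obeys the
#' tortuosity rule `d_perp = d_par * (1 - ndi)`.
#'
#' @param ndi intra-neurite volume fraction in `[0, 1]`.
#' @param odi orientation dispersion index in `(0, 1]`.
#' @param f_iso free-water volume fraction in `[0, 1]`.
#' @param b b-values per volume (s/mm^2).
#' @param cosang cosine of gradient/mean-direction angle per volume.
#' @param d_par intrinsic parallel diffusivity (mm^2/s).
#' @param d_iso free-water diffusivity (mm^2/s).
#' @return normalised signal per volume.
#' @export
noddi_signal <- function(ndi, odi, f_iso, b, cosang,
                         d_par = D_PAR_DEFAULT, d_iso = D_ISO_DEFAULT) {
  stopifnot(ndi >= 0, ndi <= 1, f_iso >= 0, f_iso <= 1)
  kappa <- odi_to_kappa(odi)
  a_i <- watson_stick_attenuation(b * d_par, kappa, cosang)
  tau <- watson_tau(kappa)
  d_perp <- d_par * (1 - ndi)
  q <- (d_par - d_perp) * (tau * cosang^2 + (1 - tau) * (1 - cosang^2) / 2) +
    d_perp
  a_e <- exp(-b * q)
  (1 - f_iso) * (ndi * a_i + (1 - ndi) * a_e) + f_iso * exp(-b * d_iso)
}

#' Simulate a multi-shell DWI series over a parameter grid
#'
#' Generates a normalised 4-D signal volume from per-voxel tissue
#' parameters under the three-compartment model, optionally corrupted by
#' Rician noise (`|S + sigma*(z1 + i z2)|` with `sigma = 1/snr`, SNR
#' defined on the b = 0 signal).
#'
#' @param params list with 3-D arrays (or scalars) `ndi`, `odi`, `f_iso`,
#'   and `mu` — either a single unit 3-vector used everywhere or a 4-D
#'   array (x, y, z, 3) of unit mean directions.
#' @param scheme a [gradient_scheme()].
#' @param affine 4x4 voxel-to-world affine for the output volume.
#' @param snr b = 0 signal-to-noise ratio, or `NULL` for noise-free.
#' @param seed integer RNG seed (noise only).
#' @param d_par,d_iso model diffusivities (mm^2/s).
#' @return a 4-D [metric_volume()] of normalised signals.
#' @export
simulate_dwi <- function(params, scheme, affine = diag(4), snr = NULL,
                         seed = 1L, d_par = D_PAR_DEFAULT,
                         d_iso = D_ISO_DEFAULT) {
  shape <- dim(as.array(params$ndi))
  if (is.null(shape)) shape <- c(1L, 1L, 1L)
  as3d <- function(x) {
    if (length(x) == 1) array(x, shape) else {
      if (!identical(dim(as.array(x)), shape)) {
        stop("parameter grids must share one shape")
      }
      as.array(x)
    }
  }
  ndi <- as3d(params$ndi); odi <- as3d(params$odi)
  f_iso <- as3d(params$f_iso)
  if (sum(scheme$b <= B_SHELL_TOL) < 1) stop("scheme needs >= 1 b=0 volume")
  mu <- params$mu %||% c(0, 0, 1)
  mu_grid <- length(dim(as.array(mu))) == 4
  g <- as.matrix(scheme[, c("gx", "gy", "gz")])
  nvol <- nrow(g)
  nvox <- prod(shape)
  sig <- matrix(0, nvox, nvol)
  for (v in seq_len(nvox)) {
    mv <- if (mu_grid) {
      ijk <- arrayInd(v, shape)
      mu[ijk[1], ijk[2], ijk[3], ]
    } else mu
    mv <- mv / sqrt(sum(mv^2))
    cosang <- as.numeric(g %*% mv)
    sig[v, ] <- noddi_signal(ndi[v], odi[v], f_iso[v], scheme$b, cosang,
                             d_par = d_par, d_iso = d_iso)
  }
  if (!is.null(snr)) {
    set.seed(seed)
    sigma <- 1 / snr
    sig <- sqrt((sig + stats::rnorm(length(sig), sd = sigma))^2 +
                  stats::rnorm(length(sig), sd = sigma)^2)
  }
  metric_volume(array(sig, c(shape, nvol)), affine)
}
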