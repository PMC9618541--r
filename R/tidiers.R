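#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tensor fit
#'
#' @param x a `tensor_fit`.
#' @param ... unused.
#' @return one-row tibble of the scalar metrics and eigenvalues.
#' @export
tidy.tensor_fit <- function(x, ...) {
  m <- tensor_metrics(x)
  tibble::tibble(fa = m$fa, md = m$md, ad = m$ad, rd = m$rd,
                 lambda1 = x$lambda[1], lambda2 = x$lambda[2],
                 lambda3 = x$lambda[3], s0 = x$s0)
}

#' @rdname tidy.tensor_fit
#' @export
glance.tensor_fit <- function(x, ...) {
  tibble::tibble(n_dropped = x$n_dropped, n_negative_ev = x$n_negative_ev)
}

#' Tidy a NODDI fit
#'
#' @param x a `noddi_fit`.
#' @param ... unused.
#' @return one-row tibble of the fitted parameters.
#' @export
tidy.noddi_fit <- function(x, ...) {
  tibble::tibble(ndi = x$ndi, odi = x$odi, f_iso = x$f_iso)
}

#' @rdname tidy.noddi_fit
#' @export
glance.noddi_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, unidentifiable = x$unidentifiable)
}

#' Tidy an adult reference distribution
#'
#' @param x an `adult_reference`.
#' @param ... unused.
#' @return tibble with one row per metric: mean and SD.
#' @export
tidy.adult_reference <- function(x, ...) {
  tibble::tibble(bundle = x$bundle, metric = x$metrics, mean = unname(x$mu),
                 sd = sqrt(diag(x$sigma)))
}

#' @rdname tidy.adult_reference
#' @export
glance.adult_reference <- function(x, ...) {
  tibble::tibble(bundle = x$bundle, n = x$n, condition = x$condition)
}

#' Tidy a maturation analysis
#'
#' @param x a `maturation_result`.
#' @param ... unused.
#' @return the per-neonate, per-bundle distance tibble.
#' @export
tidy.maturation_result <- function(x, ...) x$distances

#' @rdname tidy.maturation_result
#' @export
glance.maturation_result <- function(x, ...) {
  dplyr::left_join(x$ranking, x$spearman, by = "bundle") |>
    dplyr::rename(spearman_rho = "rho", spearman_p = "p")
}
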