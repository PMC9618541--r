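# shared fixtures: tiny random geometry builders used across test files

random_tractogram <- function(n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tractogram(lapply(seq_len(n), function(i) {
    matrix(stats::rnorm(3 * sample(2:8, 1), sd = 20), ncol = 3)
  }))
}

random_volume <- function(shape = c(4, 5, 6), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aff <- diag(c(stats::runif(3, 0.5, 3), 1))
  aff[1:3, 4] <- stats::rnorm(3, sd = 10)
  metric_volume(array(stats::rnorm(prod(shape)), shape), aff)
}

# three-shell scheme small enough for fast tensor/NODDI tests
small_scheme <- function(ndir = c(6, 24, 24), shells = c(0, 1000, 2600)) {
  gradient_scheme(rep(shells, ndir),
                  do.call(rbind, lapply(seq_along(shells), function(i) {
                    if (shells[i] == 0) matrix(0, ndir[i], 3) else
                      slfmature:::fibonacci_sphere(ndir[i], phase = i)
                  })))
}

# build (ages, values) whose sample Pearson correlation is exactly r
make_corr_sample <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(seq_len(n))[, 1]
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / sqrt(sum(e^2) / (n - 1))
  list(ages = x, values = r * x + sqrt(1 - r^2) * e)
}

# independent per-vertex boolean selection oracle (no supersampling):
# direct affine inverse + floor(c + 0.5) + 3-D array indexing
oracle_select <- function(trk, include, exclude, layout) {
  inv <- solve(layout$volume$affine)
  lab <- layout$volume$data
  d <- dim(lab)
  ids <- layout$labels
  vapply(trk$streamlines, function(s) {
    idx <- floor(t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4]) + 0.5)
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 &
      idx[, 2] < d[2] & idx[, 3] >= 0 & idx[, 3] < d[3]
    touched <- unique(lab[idx[ok, , drop = FALSE] + 1])
    all(ids[include] %in% touched) && !any(ids[exclude] %in% touched)
  }, logical(1))
}
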