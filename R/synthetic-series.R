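#' Specification for synthetic regional series
#'
#' Describes interannual regional series (one value per variable per
#' year) built as a linear trend plus correlated Gaussian noise. The
#' noise vectors of all variables share a target pairwise Pearson
#' correlation, achieved by a Cholesky factor construction, so the
#' sample correlation converges to `cross_corr` as `n_years` grows.
#'
#' @param n_years Number of years (default 14, emulating a 2007-2020
#'   record).
#' @param start_year First (base) year.
#' @param slopes Named numeric vector: prescribed trend per year for each
#'   variable (units per year).
#' @param noise_sd Noise sd per variable; recycled to the number of
#'   variables.
#' @param cross_corr Target Pearson correlation between the noise of
#'   every variable pair, in `[-1, 1]` (and > `-1/(k-1)` for `k`
#'   variables so the correlation matrix is valid).
#' @param seed Integer seed; same seed, same series.
#'
#' @return An object of class `series_spec`.
#' @seealso [make_series()]
#' @export
series_spec <- function(n_years = 14, start_year = 2007,
                        slopes = c(NPP = -5.8, DDF = -0.2, NIT = -0.1),
                        noise_sd = 1, cross_corr = 0.7, seed = 1L) {
  if (n_years < 3) stop("`n_years` must be >= 3", call. = FALSE)
  if (abs(cross_corr) > 1) stop("|cross_corr| must be <= 1", call. = FALSE)
  k <- length(slopes)
  if (k > 1 && cross_corr <= -1 / (k - 1)) {
    stop("`cross_corr` too negative for ", k, " variables", call. = FALSE)
  }
  if (is.null(names(slopes))) {
    names(slopes) <- paste0("var", seq_along(slopes))
  }
  structure(list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    slopes = slopes, noise_sd = rep_len(noise_sd, k),
    cross_corr = cross_corr, seed = as.integer(seed)
  ), class = "series_spec")
}

#' Generate correlated regional series with prescribed trends
#'
#' Each variable `v` is generated as
#' `slope_v * (year - start_year) + noise_sd_v * e_v(t)`, where the
#' `e_v(t)` are standard Gaussian with pairwise correlation
#' `cross_corr` obtained by multiplying i.i.d. normals with the Cholesky
#' factor of the equicorrelation matrix. Noiseless specs therefore
#' recover the prescribed slopes exactly, and at large `n_years` the
#' sample correlation of any detrended pair approaches `cross_corr`.
#'
#' @param spec A [series_spec()].
#' @return A tibble with columns `year`, `variable`, `value` (class
#'   `regional_series` is not assigned here; this is the plain series
#'   form consumed by [region_report()] after adding a `region` column).
#' @examples
#' s <- make_series(series_spec(noise_sd = 0, slopes = c(DDF = -5.8)))
#' coef(lm(value ~ I(year - 2007), data = s))[2]
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  k <- length(spec$slopes)
  n <- spec$n_years
  t_idx <- seq_len(n) - 1L
  corr <- matrix(spec$cross_corr, k, k); diag(corr) <- 1
  # symmetric square root: valid for the full PSD range of the
  # equicorrelation matrix, including the singular |rho| = 1 edge
  ev <- eigen(corr, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  with_seed(spec$seed, {
    e <- matrix(rnorm(n * k), n, k) %*% L       # rows ~ N(0, corr)
    vals <- vapply(seq_len(k), function(v) {
      spec$slopes[v] * t_idx + spec$noise_sd[v] * e[, v]
    }, numeric(n))
    tibble::tibble(
      year = rep(spec$start_year + t_idx, times = k),
      variable = rep(names(spec$slopes), each = n),
      value = as.vector(vals)
    )
  })
}
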