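#' Ordinary least-squares trend of an annual series
#'
#' Slope and intercept of `values` regressed on the year index, with the
#' first supplied year as base (index 0), so the intercept is the fitted
#' base-year value and the slope is in units per year. Missing values
#' are dropped pairwise.
#'
#' @param years Calendar years.
#' @param values Annual values.
#' @return List with `slope`, `intercept`, `n`; all `NA` when fewer than
#'   3 complete pairs remain.
#' @examples
#' trend_slope(2007:2020, -0.02 * (0:13) + 0.5)
#' @export
trend_slope <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  if (sum(ok) < 3) return(list(slope = NA_real_, intercept = NA_real_,
                               n = sum(ok)))
  t0 <- years[ok] - min(years[ok])
  fit <- lm(values[ok] ~ t0)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = sum(ok))
}

# Tier label from a two-sided p-value: confidence levels 99/95/90%.
mk_tier <- function(p) {
  if (is.na(p)) return("none")
  if (p < 0.01) "99" else if (p < 0.05) "95" else if (p < 0.1) "90" else "none"
}

#' Mann-Kendall monotonic trend test
#'
#' Classic (non-seasonal) Mann-Kendall test: the statistic
#' `S = sum_{i<j} sign(y_j - y_i)` is compared with its null variance
#' `[n(n-1)(2n+5) - sum_k t_k(t_k-1)(2t_k+5)] / 18` (the sum correcting
#' for groups of `t_k` tied values) through the normal approximation
#' with a continuity correction of one unit. Two-sided p-values; the
#' significance tier is `"99"`, `"95"`, `"90"` or `"none"` at
#' p < 0.01 / 0.05 / 0.1.
#'
#' @param values Annual series (missing values dropped); at least 4
#'   finite values required.
#' @return List with `s`, `var_s`, `z`, `p`, `tier`, `n`.
#' @examples
#' mann_kendall(c(1, 2, 3, 4))  # S = 6, tier "90"
#' @export
mann_kendall <- function(values) {
  y <- values[is.finite(values)]
  n <- length(y)
  if (n < 4) {
    return(list(s = NA_real_, var_s = NA_real_, z = NA_real_,
                p = NA_real_, tier = "none", n = n))
  }
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(y[(i + 1):n] - y[i]))
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) {
    return(list(s = s, var_s = var_s, z = 0, p = 1, tier = "none", n = n))
  }
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * pnorm(-abs(z))
  list(s = s, var_s = var_s, z = z, p = p, tier = mk_tier(p), n = n)
}

#' Sen's slope (median of pairwise slopes)
#'
#' Nonparametric alternative to the OLS trend, offered as an option; the
#' default trend estimator in this package is OLS.
#'
#' @inheritParams trend_slope
#' @return Median pairwise slope, units per year.
#' @export
sen_slope <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  y <- values[ok]; t <- years[ok]
  n <- length(y)
  if (n < 3) return(NA_real_)
  ij <- utils::combn(n, 2)
  median((y[ij[2, ]] - y[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
}

#' Combined trend result (OLS slope + Mann-Kendall significance)
#'
#' @inheritParams trend_slope
#' @param method Slope estimator: `"ols"` (default) or `"sen"`.
#' @return Tibble row: `slope`, `intercept`, `s`, `var_s`, `z`, `p`,
#'   `tier`, `n`.
#' @export
trend_test <- function(years, values, method = c("ols", "sen")) {
  method <- match.arg(method)
  ls <- trend_slope(years, values)
  mk <- mann_kendall(values[is.finite(years)])
  slope <- if (method == "sen") sen_slope(years, values) else ls$slope
  tibble::tibble(slope = slope, intercept = ls$intercept,
                 s = mk$s, var_s = mk$var_s, z = mk$z, p = mk$p,
                 tier = mk$tier, n = ls$n)
}

#' Anomalies about the multi-year mean
#'
#' Subtracts the long-term mean: per variable for a vector, per cell
#' (over the last dimension) for a 3-D stack. Complete series therefore
#' have anomalies summing to zero, and trends are unchanged by the
#' centring.
#'
#' @param x Numeric vector or array `[nlon, nlat, nyear]`.
#' @return Same shape as `x`.
#' @export
anomaly <- function(x) {
  if (is.null(dim(x))) return(x - mean(x, na.rm = TRUE))
  clim <- apply(x, c(1, 2), mean, na.rm = TRUE)
  sweep(x, c(1, 2), clim, `-`)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y Numeric vectors; pairs with any missing value are dropped.
#' @return Tibble row: `r`, `p`, `n`; `NA` when fewer than 3 complete
#'   pairs remain or either input has zero variance.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Cell-wise trend of a yearly field stack
#'
#' Applies [trend_slope()] and [mann_kendall()] to every grid cell of an
#' annual stack, returning slope, p-value and significance-tier rasters
#' (the map behind marking 99% cells with stars, 95% with circles and
#' 90% with triangles).
#'
#' @param stack Array `[nlon, nlat, nyear]`.
#' @param years Calendar years matching the last dimension.
#' @return List of matrices `slope`, `p`, `z` and character matrix
#'   `tier`; cells with fewer than 3 (slope) / 4 (test) finite years are
#'   missing.
#' @export
gridded_trend <- function(stack, years) {
  if (length(dim(stack)) != 3 || dim(stack)[3] != length(years)) {
    stop("`stack` must be [nlon, nlat, nyear] matching `years`",
         call. = FALSE)
  }
  nlon <- dim(stack)[1]; nlat <- dim(stack)[2]
  slope <- p <- z <- matrix(NA_real_, nlon, nlat)
  tier <- matrix("none", nlon, nlat)
  for (j in seq_len(nlat)) for (i in seq_len(nlon)) {
    y <- stack[i, j, ]
    if (sum(is.finite(y)) < 3) next
    slope[i, j] <- trend_slope(years, y)$slope
    mk <- mann_kendall(y)
    p[i, j] <- mk$p; z[i, j] <- mk$z; tier[i, j] <- mk$tier
  }
  list(slope = slope, p = p, z = z, tier = tier)
}
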