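#' Define an analysis region
#'
#' @param name Region label (e.g. `"WAS"`, `"CAS"`, `"EAS"`).
#' @param lat_bounds,lon_bounds Length-2 bounds in degrees; cells whose
#'   centres fall inside are included.
#' @param ocean_only If `TRUE`, land-masked cells are excluded from
#'   regional means.
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, lat_bounds = c(10, 20), lon_bounds,
                       ocean_only = TRUE) {
  if (lat_bounds[1] >= lat_bounds[2] || lon_bounds[1] >= lon_bounds[2]) {
    stop("region bounds must satisfy lo < hi", call. = FALSE)
  }
  structure(list(name = name, lat_bounds = lat_bounds,
                 lon_bounds = lon_bounds, ocean_only = ocean_only),
            class = "region_def")
}

#' Default western / central / eastern Arabian Sea regions
#'
#' Three contiguous, non-overlapping sectors of the 10-20 degN dust
#' deposition band. The latitude band follows the heavy-deposition belt;
#' the longitude splits (50-58, 58-66, 66-74 degE) are this package's
#' configurable convention for partitioning the basin into western,
#' central and eastern sectors, not externally prescribed values.
#'
#' @return Named list of [region_def()] objects (`WAS`, `CAS`, `EAS`).
#' @export
default_regions <- function() {
  list(
    WAS = region_def("WAS", c(10, 20), c(50, 58)),
    CAS = region_def("CAS", c(10, 20), c(58, 66)),
    EAS = region_def("EAS", c(10, 20), c(66, 74))
  )
}

#' Area-weighted regional mean of a gridded stack
#'
#' Averages the cells whose centres fall inside the region, weighting by
#' `cos(latitude)` (proportional to cell area on the regular grid), per
#' time step.
#'
#' @param stack Array `[nlon, nlat, ntime]` or matrix `[nlon, nlat]`.
#' @param grid A [grid_def()].
#' @param region A [region_def()].
#' @param ocean_mask Optional logical `[nlon, nlat]`; only `TRUE` cells
#'   contribute when the region is ocean-only.
#' @return Numeric vector of length `ntime` (or a scalar for matrix
#'   input).
#' @export
regional_mean <- function(stack, grid, region, ocean_mask = NULL) {
  stopifnot(inherits(region, "region_def"))
  was_mat <- length(dim(stack)) == 2
  if (was_mat) stack <- array(stack, c(dim(stack), 1))
  isel <- which(grid$lon_c > region$lon_bounds[1] &
                  grid$lon_c < region$lon_bounds[2])
  jsel <- which(grid$lat_c > region$lat_bounds[1] &
                  grid$lat_c < region$lat_bounds[2])
  if (length(isel) == 0 || length(jsel) == 0) {
    stop("region ", region$name, " does not intersect the grid",
         call. = FALSE)
  }
  w <- matrix(rep(cos(.deg2rad(grid$lat_c[jsel])), each = length(isel)),
              length(isel), length(jsel))
  if (region$ocean_only && !is.null(ocean_mask)) {
    w[!ocean_mask[isel, jsel, drop = FALSE]] <- 0
  }
  out <- vapply(seq_len(dim(stack)[3]), function(t) {
    v <- stack[isel, jsel, t, drop = FALSE]
    dim(v) <- dim(w)
    ok <- !is.na(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  if (was_mat) out[1] else out
}

#' Percent reduction between two values
#'
#' `100 * (a - b) / a`: by how many percent `b` falls below the
#' reference `a`. Scale-invariant in the common factor of `a` and `b`.
#'
#' @param value_a Reference (must be `> 0`).
#' @param value_b Comparison value.
#' @return Percent; `NA` (with warning) when the reference is not
#'   positive.
#' @examples
#' reduction_percent(479.87, 205.74)  # NPP drop west -> east, ~57%
#' @export
reduction_percent <- function(value_a, value_b) {
  out <- ifelse(is.na(value_a) | value_a <= 0, NA_real_,
                100 * (value_a - value_b) / value_a)
  if (any(is.na(out) & !is.na(value_a))) {
    warning("non-positive reference value; reduction undefined",
            call. = FALSE)
  }
  out
}

#' Regional climatology, anomaly trends, and cross-correlations
#'
#' Produces, per region, the summary block used to relate dust
#' deposition to ocean biology: the climatological mean and sd of each
#' variable; the interannual anomaly trend of each variable (OLS slope
#' with Mann-Kendall significance tier); and Pearson correlations of the
#' anomaly series of a focal variable (default `"NPP"`) against every
#' other variable, on their common years. Variables may cover different
#' year ranges (e.g. a nitrate record ending earlier); years are matched
#' per variable pair.
#'
#' @param series Tibble with columns `region`, `year`, `variable`,
#'   `value` (one row per region/year/variable).
#' @param focal Variable to correlate against the others.
#' @return List of tibbles: `climatology` (`region`, `variable`, `mean`,
#'   `sd`, `n_years`), `trends` (anomaly trend per region/variable:
#'   `slope`, `p`, `tier`, `n`), `correlations` (`region`, `var_x`,
#'   `var_y`, `r`, `p`, `n`).
#' @export
region_report <- function(series, focal = "NPP") {
  need <- c("region", "year", "variable", "value")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  regions <- unique(series$region)
  clim <- list(); trend <- list(); corr <- list()
  for (rg in regions) {
    sub <- series[series$region == rg, ]
    vars <- unique(sub$variable)
    for (v in vars) {
      sv <- sub[sub$variable == v, ]
      clim[[length(clim) + 1]] <- tibble::tibble(
        region = rg, variable = v,
        mean = mean(sv$value, na.rm = TRUE),
        sd = sd(sv$value, na.rm = TRUE),
        n_years = sum(is.finite(sv$value)))
      tt <- trend_test(sv$year, anomaly(sv$value))
      trend[[length(trend) + 1]] <- tibble::tibble(
        region = rg, variable = v, slope = tt$slope, p = tt$p,
        tier = tt$tier, n = tt$n)
    }
    if (focal %in% vars) {
      sf <- sub[sub$variable == focal, ]
      for (v in setdiff(vars, focal)) {
        sv <- sub[sub$variable == v, ]
        yrs <- intersect(sf$year, sv$year)
        pc <- pearson_cor(
          anomaly(sf$value[match(yrs, sf$year)]),
          anomaly(sv$value[match(yrs, sv$year)]))
        corr[[length(corr) + 1]] <- tibble::tibble(
          region = rg, var_x = focal, var_y = v,
          r = pc$r, p = pc$p, n = pc$n)
      }
    }
  }
  list(climatology = do.call(rbind, clim),
       trends = do.call(rbind, trend),
       correlations = if (length(corr)) do.call(rbind, corr) else
         tibble::tibble(region = character(), var_x = character(),
                        var_y = character(), r = numeric(),
                        p = numeric(), n = integer()))
}
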