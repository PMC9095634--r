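#' Dust deposition flux by the flux-divergence method
#'
#' Assuming no dust escapes through the top of the atmosphere and no
#' surface sources over the ocean, the deposition into a grid cell is
#' the net convergence of the column-integrated horizontal dust mass
#' fluxes: raw deposition = inflow minus outflow through the four cell
#' faces. Face fluxes are the arithmetic mean of the two adjacent
#' cell-centre column fluxes (second-order centred); at the domain edge
#' the face value is obtained by one-sided linear extrapolation from the
#' two nearest cells, which keeps the scheme second order while
#' preserving the telescoping property: the domain-total raw deposition
#' equals boundary inflow minus outflow exactly. Meridional faces have
#' length `R * dlat`, zonal faces `R * dlon * cos(lat)` (radians).
#'
#' Cells where the raw divergence is negative (apparent mass production,
#' not physical for an inert tracer over ocean) are flagged and excluded
#' from deposition totals - treated as zero deposition - but the raw
#' values are retained for diagnostics.
#'
#' @param flux_field A [flux_profiles()] result.
#' @param ocean_mask Logical matrix `[nlon, nlat]`, `TRUE` for ocean;
#'   land cells carry no deposition. Default: all ocean.
#' @return An object of class `deposition_field`: per cell/month arrays
#'   `ddf` (clipped deposition, g/s), `raw` (signed divergence, g/s),
#'   `ddf_area` (g m^-2 day^-1), `negative_flag`, plus a `totals` tibble
#'   per month (clipped and net bookkeeping, Tg/yr) and a `budget` list
#'   (boundary inflow/outflow, g/s, averaged over months).
#' @export
divergence_deposition <- function(flux_field, ocean_mask = NULL) {
  stopifnot(inherits(flux_field, "flux_field"))
  g <- flux_field$grid
  if (g$nlon < 2 || g$nlat < 2) {
    stop("divergence needs at least 2 cells in each direction",
         call. = FALSE)
  }
  if (is.null(ocean_mask)) ocean_mask <- matrix(TRUE, g$nlon, g$nlat)
  nm <- length(flux_field$months)
  area <- cell_area(g)
  Lm <- meridional_face_length(g)
  Lz_edge <- zonal_face_length(g, g$lat_edges)   # length nlat+1

  raw <- array(NA_real_, c(g$nlon, g$nlat, nm))
  bc_in <- bc_out <- numeric(nm)
  for (m in seq_len(nm)) {
    Fu <- flux_field$column_flux_u[, , m]
    Fv <- flux_field$column_flux_v[, , m]
    # Face values along lon (nlon+1 faces per row) and lat.
    fu_face <- rbind(1.5 * Fu[1, ] - 0.5 * Fu[2, ],
                     (Fu[-1, , drop = FALSE] + Fu[-g$nlon, , drop = FALSE]) / 2,
                     1.5 * Fu[g$nlon, ] - 0.5 * Fu[g$nlon - 1, ])
    fv_face <- cbind(1.5 * Fv[, 1] - 0.5 * Fv[, 2],
                     (Fv[, -1, drop = FALSE] + Fv[, -g$nlat, drop = FALSE]) / 2,
                     1.5 * Fv[, g$nlat] - 0.5 * Fv[, g$nlat - 1])
    fu_face <- fu_face * Lm                                   # g/s eastward
    fv_face <- sweep(fv_face, 2, Lz_edge, `*`)                # g/s northward
    raw[, , m] <- fu_face[seq_len(g$nlon), ] - fu_face[seq_len(g$nlon) + 1, ] +
      fv_face[, seq_len(g$nlat)] - fv_face[, seq_len(g$nlat) + 1]
    inward <- c(fu_face[1, ], -fu_face[g$nlon + 1, ],
                fv_face[, 1], -fv_face[, g$nlat + 1])
    bc_in[m] <- sum(pmax(inward, 0), na.rm = TRUE)
    bc_out[m] <- sum(pmax(-inward, 0), na.rm = TRUE)
  }
  mask3 <- array(rep(ocean_mask, nm), c(g$nlon, g$nlat, nm))
  raw[!mask3] <- NA_real_
  negative_flag <- !is.na(raw) & raw < 0
  ddf <- pmax(raw, 0)
  ddf_area <- sweep(ddf, c(1, 2), area, `/`) * 86400   # g m^-2 day^-1

  totals <- tibble::tibble(
    month = flux_field$months,
    total_clipped_Tg_yr = vapply(seq_len(nm), function(m)
      sum(ddf[, , m], na.rm = TRUE), numeric(1)) * GS_TO_TG_YR,
    total_net_Tg_yr = vapply(seq_len(nm), function(m)
      sum(raw[, , m], na.rm = TRUE), numeric(1)) * GS_TO_TG_YR,
    n_negative_cells = vapply(seq_len(nm), function(m)
      sum(negative_flag[, , m]), numeric(1))
  )
  structure(list(
    grid = g, months = flux_field$months,
    ddf = ddf, raw = raw, ddf_area = ddf_area,
    negative_flag = negative_flag, ocean_mask = ocean_mask,
    totals = totals,
    budget = list(boundary_in = mean(bc_in), boundary_out = mean(bc_out))
  ), class = "deposition_field")
}

#' @export
print.deposition_field <- function(x, ...) {
  cat(sprintf("<deposition_field> %dx%d cells x %d month(s); mean total %.4g Tg/yr (%.0f negative-flagged cells/month)\n",
              x$grid$nlon, x$grid$nlat, length(x$months),
              mean(x$totals$total_clipped_Tg_yr),
              mean(x$totals$n_negative_cells)))
  invisible(x)
}

#' Dust loss frequency
#'
#' Ratio of the area-normalized deposition flux to the column dust mass
#' loading. Both numerator and denominator scale as 1/DMEE, so the loss
#' frequency is independent of the assumed mass extinction efficiency.
#'
#' @param ddf_area Deposition flux, g m^-2 day^-1 (`>= 0`).
#' @param loading Column dust mass loading, g m^-2.
#' @return Loss frequency, per day, same shape. Zero deposition gives 0;
#'   non-positive or missing loading gives `NA` (with a warning when
#'   deposition is positive there).
#' @export
loss_frequency <- function(ddf_area, loading) {
  if (any(ddf_area < 0, na.rm = TRUE)) {
    stop("`ddf_area` must be >= 0", call. = FALSE)
  }
  bad <- !is.na(ddf_area) & ddf_area > 0 &
    (is.na(loading) | loading <= 0)
  if (any(bad)) {
    warning(sum(bad), " cell(s) with positive deposition but no loading; set to NA",
            call. = FALSE)
  }
  out <- ifelse(!is.na(loading) & loading > 0, ddf_area / loading, NA_real_)
  out[bad] <- NA_real_
  if (!is.null(dim(ddf_area))) dim(out) <- dim(ddf_area)
  out
}

#' Mass-weighted dust lifetime
#'
#' Reciprocal of the dust loss frequency: the timescale over which the
#' atmospheric dust column would be removed at the current deposition
#' rate.
#'
#' @param dlf Loss frequency, per day.
#' @return Lifetime in days; `NA` where `dlf` is missing or `<= 0`.
#' @examples
#' dust_lifetime(c(0.5, 2.5))  # 2 days, 0.4 days
#' @export
dust_lifetime <- function(dlf) {
  out <- ifelse(!is.na(dlf) & dlf > 0, 1 / dlf, NA_real_)
  if (!is.null(dim(dlf))) dim(out) <- dim(dlf)
  out
}

#' Seasonal aggregation of a monthly field stack
#'
#' Averages a monthly per-cell array into a multi-year seasonal
#' climatology: months of each season are first averaged within a
#' season-year (December counts with the following winter), then the
#' mean and standard deviation are taken across season-years.
#'
#' @param x Array `[nlon, nlat, nmonth]` (or a vector of domain totals
#'   of length `nmonth`).
#' @param months Month labels `"YYYY-MM"` matching the last dimension.
#' @param season One of `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @return List with `mean` and `sd` (per cell, or scalars for vector
#'   input), `n_years`, and `coverage` (mean number of months available
#'   per season-year, out of 3).
#' @export
seasonal_aggregate <- function(x, months, season) {
  if (!season %in% c("DJF", "MAM", "JJA", "SON")) {
    stop("unknown season label: ", season, call. = FALSE)
  }
  sel <- which(season_of(months) == season)
  if (length(sel) == 0) stop("no months of season ", season, call. = FALSE)
  syr <- season_year(months[sel])
  years <- sort(unique(syr))
  vec_in <- is.null(dim(x))
  if (vec_in) x <- array(x, c(1, 1, length(x)))
  per_year <- array(NA_real_, c(dim(x)[1], dim(x)[2], length(years)))
  for (yi in seq_along(years)) {
    msel <- sel[syr == years[yi]]
    sl <- x[, , msel, drop = FALSE]
    all_na <- apply(is.na(sl), c(1, 2), all)
    mu <- apply(sl, c(1, 2), mean, na.rm = TRUE)
    mu[all_na] <- NA_real_
    per_year[, , yi] <- mu
  }
  mean_f <- apply(per_year, c(1, 2), mean, na.rm = TRUE)
  sd_f <- apply(per_year, c(1, 2), sd, na.rm = TRUE)
  mean_f[apply(is.na(per_year), c(1, 2), all)] <- NA_real_
  if (vec_in) { mean_f <- mean_f[1, 1]; sd_f <- sd_f[1, 1] }
  list(mean = mean_f, sd = sd_f, n_years = length(years),
       coverage = length(sel) / (3 * length(years)))
}
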