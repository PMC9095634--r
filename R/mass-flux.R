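#' Mass-flux parameters
#'
#' @param dmee Dust mass extinction efficiency, m^2/g (default 0.37, the
#'   550 nm value estimated over the eastern tropical Atlantic, assumed
#'   independent of altitude and relative humidity).
#' @param z_top Column integration ceiling, metres: altitude bins with
#'   midpoints at or above this height do not contribute to column
#'   fluxes or loading (default 7000 m).
#' @return An object of class `flux_params`.
#' @export
flux_params <- function(dmee = 0.37, z_top = 7000) {
  if (dmee <= 0) stop("`dmee` must be > 0", call. = FALSE)
  if (z_top <= 0) stop("`z_top` must be > 0", call. = FALSE)
  structure(list(dmee = dmee, z_top = z_top), class = "flux_params")
}

#' Monthly gridded wind profiles
#'
#' Container for wind vectors co-registered to a dust grid: one zonal and
#' one meridional component per cell, altitude bin and month.
#'
#' @param grid A [grid_def()].
#' @param months Character vector of `"YYYY-MM"` labels.
#' @param u,v Arrays `[nlon, nlat, nalt, nmonth]`, m/s.
#' @return An object of class `wind_field`.
#' @export
wind_field <- function(grid, months, u, v) {
  expect_dim <- c(grid$nlon, grid$nlat, grid$nalt, length(months))
  if (!identical(dim(u), as.integer(expect_dim)) &&
      !identical(dim(u), expect_dim)) {
    stop("`u` must have dim [", paste(expect_dim, collapse = ", "), "], got [",
         paste(dim(u), collapse = ", "), "]", call. = FALSE)
  }
  if (!identical(dim(v), dim(u))) {
    stop("`u` and `v` dimensions differ", call. = FALSE)
  }
  structure(list(grid = grid, months = months, u = u, v = v),
            class = "wind_field")
}

#' Interpolate source-level winds onto the grid's altitude bins
#'
#' Winds delivered on arbitrary (e.g. pressure-derived) altitude levels
#' are linearly interpolated in altitude to the dust grid's bin
#' midpoints, per cell and month; outside the source range the nearest
#' level is held constant.
#'
#' @param grid A [grid_def()].
#' @param months Month labels.
#' @param z_src Source altitudes, metres, increasing.
#' @param u_src,v_src Arrays `[nlon, nlat, n_src, nmonth]`.
#' @return A [wind_field()] on the grid's altitude bins.
#' @export
regrid_winds <- function(grid, months, z_src, u_src, v_src) {
  if (any(diff(z_src) <= 0)) stop("`z_src` must be increasing", call. = FALSE)
  interp1 <- function(arr) {
    out <- array(NA_real_, c(grid$nlon, grid$nlat, grid$nalt, length(months)))
    for (m in seq_along(months)) for (j in seq_len(grid$nlat)) {
      for (i in seq_len(grid$nlon)) {
        out[i, j, , m] <- approx(z_src, arr[i, j, , m], xout = grid$alt_mid,
                                 rule = 2)$y
      }
    }
    out
  }
  wind_field(grid, months, interp1(u_src), interp1(v_src))
}

#' Dust mass concentration from extinction
#'
#' `DMC = DExt / DMEE`, with extinction converted to per metre first.
#'
#' @param dext Dust extinction in Mm^-1 (`NA` propagates).
#' @param dmee Dust mass extinction efficiency, m^2/g.
#' @return Mass concentration, g/m^3, same shape.
#' @examples
#' mass_concentration(37, 0.37)  # 37 Mm^-1 = 3.7e-5 m^-1 -> 1e-4 g/m^3
#' @export
mass_concentration <- function(dext, dmee = 0.37) {
  if (dmee <= 0) stop("`dmee` must be > 0", call. = FALSE)
  if (any(dext < 0, na.rm = TRUE)) stop("`dext` must be >= 0", call. = FALSE)
  (dext * 1e-6) / dmee
}

#' Build dust mass-flux profiles from the dust grid and winds
#'
#' Converts gridded dust extinction to mass concentration, multiplies by
#' the co-registered wind components to obtain per-layer flux densities,
#' and integrates vertically: layer flux = density x layer thickness,
#' column flux = sum of layer fluxes over bins with midpoints below the
#' ceiling. Also computes the column dust mass loading
#' (`loading = DOD / DMEE` cell by cell).
#'
#' @param dust_grid A `dust_grid` (from [grid_monthly()] or
#'   [plume_to_inputs()]).
#' @param winds A [wind_field()] on the same grid and months.
#' @param params A [flux_params()].
#' @return An object of class `flux_field` with arrays `dmc` (g/m^3),
#'   `flux_u`/`flux_v` (flux density, g m^-2 s^-1), `layer_flux_u`/`_v`
#'   (g m^-1 s^-1), `column_flux_u`/`_v` `[nlon, nlat, nmonth]`
#'   (g m^-1 s^-1), and `loading` (g/m^2).
#' @export
flux_profiles <- function(dust_grid, winds, params = flux_params()) {
  stopifnot(inherits(dust_grid, "dust_grid"), inherits(winds, "wind_field"))
  g <- dust_grid$grid
  if (!identical(dim(winds$u), dim(dust_grid$dext))) {
    stop("wind/dust grid mismatch: winds [",
         paste(dim(winds$u), collapse = ", "), "] vs dust [",
         paste(dim(dust_grid$dext), collapse = ", "), "]", call. = FALSE)
  }
  if (!identical(winds$months, dust_grid$months)) {
    stop("wind/dust month labels differ", call. = FALSE)
  }
  dmc <- mass_concentration(dust_grid$dext, params$dmee)
  fu <- dmc * winds$u
  fv <- dmc * winds$v
  lay_u <- sweep(fu, 3, g$dz, `*`)
  lay_v <- sweep(fv, 3, g$dz, `*`)
  in_col <- g$alt_mid < params$z_top

  col_sum <- function(lay) {
    nm <- length(dust_grid$months)
    out <- array(NA_real_, c(g$nlon, g$nlat, nm))
    for (m in seq_len(nm)) {
      sl <- lay[, , in_col, m, drop = FALSE]
      dim(sl) <- c(g$nlon, g$nlat, sum(in_col))
      all_na <- apply(is.na(sl), c(1, 2), all)
      s <- apply(sl, c(1, 2), sum, na.rm = TRUE)
      s[all_na] <- NA_real_
      out[, , m] <- s
    }
    out
  }
  lay_mass <- sweep(dmc, 3, g$dz, `*`)
  structure(list(
    grid = g, months = dust_grid$months, params = params,
    dmc = dmc, flux_u = fu, flux_v = fv,
    layer_flux_u = lay_u, layer_flux_v = lay_v,
    column_flux_u = col_sum(lay_u), column_flux_v = col_sum(lay_v),
    loading = col_sum(lay_mass)
  ), class = "flux_field")
}

#' @export
print.flux_field <- function(x, ...) {
  cat(sprintf("<flux_field> %dx%d cells x %d month(s), DMEE %g m2/g; mean |column flux| %.4g g m-1 s-1\n",
              x$grid$nlon, x$grid$nlat, length(x$months), x$params$dmee,
              mean(sqrt(x$column_flux_u^2 + x$column_flux_v^2), na.rm = TRUE)))
  invisible(x)
}

#' Define a boundary transect
#'
#' A transect is a line of cell faces along which dust mass flux is
#' accumulated. A *meridional* transect runs north-south at a fixed
#' longitude and is crossed by the zonal flux; a *zonal* transect runs
#' east-west at a fixed latitude and is crossed by the meridional flux.
#' The default sign convention is positive for eastward (meridional
#' transect) or northward (zonal transect) transport; set
#' `positive_inward = -1` to flip (e.g. to count influx into a box as
#' positive on its eastern or northern boundary).
#'
#' @param name Label.
#' @param orientation `"meridional"` or `"zonal"` (orientation of the
#'   line itself).
#' @param at Fixed coordinate of the line, degrees; must coincide with a
#'   grid cell edge.
#' @param span Length-2 range of the running coordinate, degrees.
#' @param positive_inward `+1` or `-1` sign flag.
#' @return An object of class `transect`.
#' @export
transect <- function(name, orientation = c("meridional", "zonal"),
                     at, span, positive_inward = 1) {
  orientation <- match.arg(orientation)
  if (length(span) != 2 || span[1] >= span[2]) {
    stop("`span` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(name = name, orientation = orientation, at = at,
                 span = span, sign = sign(positive_inward)),
            class = "transect")
}

#' Dust mass flux through a transect
#'
#' Sums flux density x face length over the faces of the transect,
#' per altitude bin and in total, converted to Tg/yr
#' (1 g/s = 3.1536e-5 Tg/yr). Face values are the mean of the two
#' adjacent cell-centre fluxes, or the single adjacent cell at the
#' domain edge. Missing cells reduce the reported coverage fraction.
#'
#' @param flux_field A [flux_profiles()] result.
#' @param tr A [transect()].
#' @param month Month label(s) to average over; default all.
#' @return A list with `per_bin` (tibble: `alt_mid_m`, `flux_Tg_yr`),
#'   `total_Tg_yr`, and `coverage` (fraction of transect faces with
#'   data).
#' @export
transect_flux <- function(flux_field, tr, month = NULL) {
  stopifnot(inherits(flux_field, "flux_field"), inherits(tr, "transect"))
  g <- flux_field$grid
  months <- flux_field$months
  if (!is.null(month)) {
    if (!all(month %in% months)) stop("unknown month label", call. = FALSE)
    msel <- match(month, months)
  } else msel <- seq_along(months)

  if (tr$orientation == "meridional") {
    edges <- g$lon_edges
    k <- which(abs(edges - tr$at) < 1e-6)
    if (length(k) != 1) stop("transect longitude is not a grid edge",
                             call. = FALSE)
    jsel <- which(g$lat_c > tr$span[1] & g$lat_c < tr$span[2])
    if (length(jsel) == 0) stop("transect span contains no cells",
                                call. = FALSE)
    lay <- flux_field$layer_flux_u
    face_len <- rep(meridional_face_length(g), length(jsel))
    get_face <- function(b, m) {
      if (k == 1) lay[1, jsel, b, m]
      else if (k == g$nlon + 1) lay[g$nlon, jsel, b, m]
      else (lay[k - 1, jsel, b, m] + lay[k, jsel, b, m]) / 2
    }
  } else {
    edges <- g$lat_edges
    k <- which(abs(edges - tr$at) < 1e-6)
    if (length(k) != 1) stop("transect latitude is not a grid edge",
                             call. = FALSE)
    jsel <- which(g$lon_c > tr$span[1] & g$lon_c < tr$span[2])
    if (length(jsel) == 0) stop("transect span contains no cells",
                                call. = FALSE)
    lay <- flux_field$layer_flux_v
    face_len <- rep(zonal_face_length(g, tr$at), length(jsel))
    get_face <- function(b, m) {
      if (k == 1) lay[jsel, 1, b, m]
      else if (k == g$nlat + 1) lay[jsel, g$nlat, b, m]
      else (lay[jsel, k - 1, b, m] + lay[jsel, k, b, m]) / 2
    }
  }

  per_bin <- numeric(g$nalt)
  n_face_data <- 0; n_face <- 0
  for (b in seq_len(g$nalt)) {
    per_month <- vapply(msel, function(m) {
      f <- get_face(b, m)
      n_face <<- n_face + length(f)
      n_face_data <<- n_face_data + sum(!is.na(f))
      sum(f * face_len, na.rm = TRUE)
    }, numeric(1))
    per_bin[b] <- mean(per_month)
  }
  per_bin <- tr$sign * per_bin * GS_TO_TG_YR
  list(
    per_bin = tibble::tibble(alt_mid_m = g$alt_mid, flux_Tg_yr = per_bin),
    total_Tg_yr = sum(per_bin),
    coverage = if (n_face > 0) n_face_data / n_face else 0
  )
}
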