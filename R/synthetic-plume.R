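#' Generate a plume scenario with analytically known deposition
#'
#' Builds a gridded dust plume (concentration per cell/layer) advected by
#' prescribed winds, together with the exact deposition field implied by
#' the divergence theorem: the truth for each cell is the net inward flux
#' through its four faces, computed by fine quadrature of the analytic
#' column-integrated flux along each face. Because every interior face is
#' shared by two cells with opposite signs, the domain-total truth equals
#' boundary inflow minus outflow to machine precision (mass closure).
#'
#' Two scenario kinds are available:
#' \describe{
#'   \item{`uniform_advection`}{Uniform wind `(u0, v0)` over a
#'     concentration decaying exponentially downwind,
#'     `C = c0 * exp(-(lon - lon_min)/decay_length_deg)`. With `u0 > 0`
#'     the column flux decreases eastward everywhere, so the implied
#'     deposition is positive in every cell - the clean oracle for the
#'     flux-divergence estimator.}
#'   \item{`gaussian_plume`}{Uniform wind over an isotropic Gaussian blob
#'     centred at `center` with sd `sigma_deg`. Deposition is positive on
#'     the downwind side and negative upwind (mass picked up), exercising
#'     the negative-divergence flagging.}
#' }
#'
#' @param kind `"uniform_advection"` or `"gaussian_plume"`.
#' @param grid A [grid_def()].
#' @param u0,v0 Wind components, m/s, applied at every cell and layer.
#' @param c0 Peak dust mass concentration, g/m^3.
#' @param decay_length_deg e-folding length (degrees longitude) of the
#'   `uniform_advection` concentration field.
#' @param center,sigma_deg Centre `c(lon, lat)` and sd (degrees) of the
#'   `gaussian_plume` concentration field.
#' @param plume_top_m Concentration fills all altitude bins whose midpoint
#'   lies below this height; zero above.
#' @param month Month label attached to the scenario fields.
#' @param n_quad Quadrature points per cell face for the truth integrals.
#'
#' @return An object of class `plume_scenario`: the grid, `concentration`
#'   `[nlon, nlat, nalt]` (g/m^3), `winds_u`/`winds_v` (m/s),
#'   `truth_deposition` `[nlon, nlat]` (g/s, signed: negative = mass
#'   uptake), and a `closure` list with boundary inflow, outflow and the
#'   total truth (all g/s).
#' @examples
#' pl <- make_plume("uniform_advection", grid_def(), u0 = 8)
#' pl$closure$total_truth - (pl$closure$boundary_in - pl$closure$boundary_out)
#' @export
make_plume <- function(kind = c("uniform_advection", "gaussian_plume"),
                       grid = grid_def(),
                       u0 = 8, v0 = 0, c0 = 1e-4,
                       decay_length_deg = 15,
                       center = NULL, sigma_deg = 8,
                       plume_top_m = 3000,
                       month = "2007-07", n_quad = 32) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "dust_grid_def"))
  stop_if_not_finite(c(u0, v0, c0), "winds and concentration")
  if (c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  if (is.null(center)) {
    center <- c(mean(range(grid$lon_edges)), mean(range(grid$lat_edges)))
  }

  conc_fun <- switch(kind,
    uniform_advection = function(lon, lat) {
      # `+ 0 * lat` keeps the field vectorized over both coordinates
      c0 * exp(-((lon + 0 * lat) - grid$lon_edges[1]) / decay_length_deg)
    },
    gaussian_plume = function(lon, lat) {
      c0 * exp(-((lon - center[1])^2 + (lat - center[2])^2) / (2 * sigma_deg^2))
    })

  in_plume <- grid$alt_mid < plume_top_m
  depth_m <- sum(grid$dz[in_plume])           # column depth holding dust
  if (depth_m <= 0) stop("`plume_top_m` is below the lowest bin midpoint",
                         call. = FALSE)

  # Column-integrated fluxes of the analytic fields, g m^-1 s^-1
  col_flux_u <- function(lon, lat) u0 * conc_fun(lon, lat) * depth_m
  col_flux_v <- function(lon, lat) v0 * conc_fun(lon, lat) * depth_m

  R <- grid$earth_radius
  nlon <- grid$nlon; nlat <- grid$nlat
  qm <- (seq_len(n_quad) - 0.5) / n_quad      # midpoint rule on (0,1)

  # Meridional faces (constant lon): total eastward flux in g/s.
  fu_face <- matrix(0, nlon + 1, nlat)
  dlat <- grid$cell_deg
  for (j in seq_len(nlat)) {
    latq <- grid$lat_edges[j] + qm * dlat
    seg <- R * .deg2rad(dlat) / n_quad
    for (i in seq_len(nlon + 1)) {
      fu_face[i, j] <- sum(col_flux_u(grid$lon_edges[i], latq)) * seg
    }
  }
  # Zonal faces (constant lat): total northward flux in g/s.
  fv_face <- matrix(0, nlon, nlat + 1)
  dlon <- grid$cell_deg
  for (j in seq_len(nlat + 1)) {
    latf <- grid$lat_edges[j]
    seg <- R * .deg2rad(dlon) * cos(.deg2rad(latf)) / n_quad
    for (i in seq_len(nlon)) {
      lonq <- grid$lon_edges[i] + qm * dlon
      fv_face[i, j] <- sum(col_flux_v(lonq, latf)) * seg
    }
  }

  truth <- fu_face[seq_len(nlon), , drop = FALSE] -
    fu_face[seq_len(nlon) + 1, , drop = FALSE] +
    fv_face[, seq_len(nlat), drop = FALSE] -
    fv_face[, seq_len(nlat) + 1, drop = FALSE]

  inward <- c(fu_face[1, ], -fu_face[nlon + 1, ],
              fv_face[, 1], -fv_face[, nlat + 1])
  closure <- list(
    boundary_in = sum(pmax(inward, 0)),
    boundary_out = sum(pmax(-inward, 0)),
    total_truth = sum(truth)
  )

  conc_c <- outer(grid$lon_c, grid$lat_c, conc_fun)
  concentration <- array(0, c(nlon, nlat, grid$nalt))
  for (k in seq_len(grid$nalt)) {
    if (in_plume[k]) concentration[, , k] <- conc_c
  }
  winds_u <- array(u0, c(nlon, nlat, grid$nalt))
  winds_v <- array(v0, c(nlon, nlat, grid$nalt))

  structure(list(
    kind = kind, grid = grid, month = month,
    concentration = concentration,
    winds_u = winds_u, winds_v = winds_v,
    plume_top_m = plume_top_m, depth_m = depth_m,
    params = list(u0 = u0, v0 = v0, c0 = c0,
                  decay_length_deg = decay_length_deg,
                  center = center, sigma_deg = sigma_deg),
    truth_deposition = truth, closure = closure
  ), class = "plume_scenario")
}

#' @export
print.plume_scenario <- function(x, ...) {
  cat(sprintf("<plume_scenario> %s on %dx%d cells; total truth deposition %.4g g/s (in %.4g, out %.4g)\n",
              x$kind, x$grid$nlon, x$grid$nlat, x$closure$total_truth,
              x$closure$boundary_in, x$closure$boundary_out))
  invisible(x)
}

#' Express a plume scenario as retrieval-stage products
#'
#' Converts a [make_plume()] scenario into the dust-extinction grid and
#' wind field that the mass-flux stage consumes, using the given mass
#' extinction efficiency to map concentration to extinction
#' (`dext = DMC * DMEE`). Running the flux and deposition stages on these
#' products with the same DMEE must reproduce the scenario's fluxes
#' exactly, which makes the scenario an end-to-end oracle.
#'
#' @param plume A `plume_scenario`.
#' @param dmee Dust mass extinction efficiency, m^2/g.
#' @return List with elements `dust_grid` (class `dust_grid`) and
#'   `winds` (class `wind_field`).
#' @export
plume_to_inputs <- function(plume, dmee = 0.37) {
  stopifnot(inherits(plume, "plume_scenario"))
  g <- plume$grid
  dext <- array(plume$concentration * dmee * 1e6,   # m^-1 -> Mm^-1
                c(g$nlon, g$nlat, g$nalt, 1))
  grid_obj <- new_dust_grid(g, plume$month, dext,
                            n_samples = array(1L, c(g$nlon, g$nlat, 1)))
  winds <- wind_field(g, plume$month,
                      u = array(plume$winds_u, c(g$nlon, g$nlat, g$nalt, 1)),
                      v = array(plume$winds_v, c(g$nlon, g$nlat, g$nalt, 1)))
  list(dust_grid = grid_obj, winds = winds)
}
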