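#' Define a regular lat/lon/altitude analysis grid
#'
#' Cell-centred regular grid used for all gridded products. The default
#' covers the study domain 0-40 degN, 30-76 degE at 2 x 2 degree
#' resolution with 1 km altitude bins from the surface to 7 km, the
#' ceiling below which transported dust is assumed to reside.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in degrees east /
#'   north. Must be multiples of nothing in particular, but
#'   `(max - min)` must be a whole number of cells.
#' @param cell_deg Horizontal cell size in degrees (same zonally and
#'   meridionally).
#' @param alt_edges Altitude bin edges in metres above mean sea level,
#'   strictly increasing.
#' @param earth_radius Spherical Earth radius in metres.
#'
#' @return An object of class `dust_grid_def`: a list with cell edges,
#'   cell centres, altitude bin midpoints and thicknesses, and counts.
#' @examples
#' g <- grid_def()
#' g$nlon; g$nlat; range(g$lat_c)
#' @export
grid_def <- function(lon_min = 30, lon_max = 76, lat_min = 0, lat_max = 40,
                     cell_deg = 2, alt_edges = seq(0, 7000, by = 1000),
                     earth_radius = 6.371e6) {
  if (lon_max <= lon_min || lat_max <= lat_min) {
    stop("grid bounds must satisfy min < max", call. = FALSE)
  }
  nlon <- (lon_max - lon_min) / cell_deg
  nlat <- (lat_max - lat_min) / cell_deg
  if (abs(nlon - round(nlon)) > 1e-9 || abs(nlat - round(nlat)) > 1e-9) {
    stop("domain extent must be a whole number of cells", call. = FALSE)
  }
  if (length(alt_edges) < 2 || any(diff(alt_edges) <= 0)) {
    stop("`alt_edges` must be strictly increasing with >= 2 edges",
         call. = FALSE)
  }
  nlon <- as.integer(round(nlon)); nlat <- as.integer(round(nlat))
  lon_edges <- seq(lon_min, lon_max, length.out = nlon + 1)
  lat_edges <- seq(lat_min, lat_max, length.out = nlat + 1)
  structure(list(
    lon_edges = lon_edges, lat_edges = lat_edges,
    lon_c = (lon_edges[-1] + lon_edges[-(nlon + 1)]) / 2,
    lat_c = (lat_edges[-1] + lat_edges[-(nlat + 1)]) / 2,
    alt_edges = alt_edges,
    alt_mid = (alt_edges[-1] + alt_edges[-length(alt_edges)]) / 2,
    dz = diff(alt_edges),
    cell_deg = cell_deg, nlon = nlon, nlat = nlat,
    nalt = length(alt_edges) - 1L,
    earth_radius = earth_radius
  ), class = "dust_grid_def")
}

#' @export
print.dust_grid_def <- function(x, ...) {
  cat(sprintf("<dust_grid_def> %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g], %d altitude bins to %g m\n",
              x$nlon, x$nlat, x$cell_deg,
              min(x$lon_edges), max(x$lon_edges),
              min(x$lat_edges), max(x$lat_edges),
              x$nalt, max(x$alt_edges)))
  invisible(x)
}

# Length (m) of a meridional cell face (constant longitude, spanning one
# cell in latitude). Meridians are great circles so this is
# latitude-independent.
meridional_face_length <- function(grid) {
  grid$earth_radius * .deg2rad(grid$cell_deg)
}

# Length (m) of a zonal cell face (constant latitude `lat_deg`, spanning
# one cell in longitude); shrinks with cos(latitude).
zonal_face_length <- function(grid, lat_deg) {
  grid$earth_radius * .deg2rad(grid$cell_deg) * cos(.deg2rad(lat_deg))
}

#' Spherical areas of grid cells
#'
#' @param grid A [grid_def()] object.
#' @return Matrix `[nlon, nlat]` of cell areas in square metres.
#' @export
cell_area <- function(grid) {
  dlam <- .deg2rad(grid$cell_deg)
  band <- grid$earth_radius^2 * dlam *
    (sin(.deg2rad(grid$lat_edges[-1])) -
       sin(.deg2rad(grid$lat_edges[-(grid$nlat + 1)])))
  matrix(band, nrow = grid$nlon, ncol = grid$nlat, byrow = TRUE)
}

# Map lon/lat coordinates to cell indices; points outside the domain get NA.
locate_cells <- function(grid, lon, lat) {
  i <- findInterval(lon, grid$lon_edges, rightmost.closed = TRUE)
  j <- findInterval(lat, grid$lat_edges, rightmost.closed = TRUE)
  i[i < 1 | i > grid$nlon] <- NA_integer_
  j[j < 1 | j > grid$nlat] <- NA_integer_
  i[is.na(j)] <- NA_integer_
  j[is.na(i)] <- NA_integer_
  list(i = i, j = j)
}

# Month label helpers: months are "YYYY-MM" strings throughout.
month_num <- function(months) as.integer(substr(months, 6, 7))
month_year <- function(months) as.integer(substr(months, 1, 4))

season_of <- function(months) {
  m <- month_num(months)
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

# Season-year convention: December is counted with the following winter.
season_year <- function(months) {
  y <- month_year(months)
  ifelse(month_num(months) == 12L, y + 1L, y)
}
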