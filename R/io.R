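#' Write a lidar granule to long-format CSV
#'
#' One row per profile/level with columns `profile`, `lat`, `lon`,
#' `month`, `altitude_m`, `beta_532`, `pdr`, `cad`. The synthetic truth
#' block is not serialized (it is not part of the observable record).
#'
#' @param granule A `lidar_granule`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_granule_csv <- function(granule, path) {
  stopifnot(inherits(granule, "lidar_granule"))
  nz <- length(granule$levels); np <- length(granule$lat)
  df <- data.frame(
    profile = rep(seq_len(np), each = nz),
    lat = rep(granule$lat, each = nz),
    lon = rep(granule$lon, each = nz),
    month = rep(granule$month, each = nz),
    altitude_m = rep(granule$levels, np),
    beta_532 = as.vector(granule$beta_p),
    pdr = as.vector(granule$pdr),
    cad = as.vector(granule$cad)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a lidar granule from long-format CSV
#'
#' Validates the schema written by [write_granule_csv()]; any missing
#' mandatory column is reported by name. All profiles must share one
#' altitude grid.
#'
#' @param path CSV file.
#' @return A `lidar_granule` (without a truth block).
#' @export
read_granule_csv <- function(path) {
  df <- read.csv(path)
  need <- c("profile", "lat", "lon", "month", "altitude_m",
            "beta_532", "pdr", "cad")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("granule file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  profs <- sort(unique(df$profile))
  z <- sort(unique(df$altitude_m))
  nz <- length(z); np <- length(profs)
  if (nrow(df) != nz * np) {
    stop("granule file is not a complete profile x level table",
         call. = FALSE)
  }
  df <- df[order(df$profile, df$altitude_m), ]
  shape <- function(col) matrix(df[[col]], nz, np)
  first_rows <- df[!duplicated(df$profile), ]
  structure(list(
    levels = z,
    lat = first_rows$lat, lon = first_rows$lon, month = first_rows$month,
    beta_p = shape("beta_532"), pdr = shape("pdr"), cad = shape("cad"),
    truth = NULL, spec = NULL
  ), class = "lidar_granule")
}

#' Write / read the monthly dust grid as long-format CSV
#'
#' Columns `month`, `lon`, `lat`, `alt_mid_m`, `dext_Mm`, `n_samples`;
#' missing cells are written as empty fields and read back as `NA`
#' (never as zero). Column optical depth is recomputed on read, so the
#' DOD/extinction consistency invariant holds for round-tripped grids.
#'
#' @param dust_grid A `dust_grid`.
#' @param path CSV file.
#' @param grid A [grid_def()] matching the file (reader argument).
#' @return `path` (writer) or a `dust_grid` (reader).
#' @export
write_dust_grid_csv <- function(dust_grid, path) {
  stopifnot(inherits(dust_grid, "dust_grid"))
  g <- dust_grid$grid
  nm <- length(dust_grid$months)
  df <- expand.grid(lon = g$lon_c, lat = g$lat_c, alt_mid_m = g$alt_mid,
                    month = dust_grid$months, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$dext_Mm <- as.vector(dust_grid$dext)
  df$n_samples <- as.vector(
    array(rep(dust_grid$n_samples, each = 1),
          c(g$nlon, g$nlat, nm))[cbind(
            match(df$lon, g$lon_c), match(df$lat, g$lat_c),
            match(df$month, dust_grid$months))])
  write.csv(df[, c("month", "lon", "lat", "alt_mid_m", "dext_Mm",
                   "n_samples")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dust_grid_csv
#' @export
read_dust_grid_csv <- function(path, grid = grid_def()) {
  df <- read.csv(path)
  need <- c("month", "lon", "lat", "alt_mid_m", "dext_Mm", "n_samples")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("dust grid file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  months <- sort(unique(df$month))
  nm <- length(months)
  dext <- array(NA_real_, c(grid$nlon, grid$nlat, grid$nalt, nm))
  nsamp <- array(0L, c(grid$nlon, grid$nlat, nm))
  i <- match(df$lon, grid$lon_c); j <- match(df$lat, grid$lat_c)
  k <- match(df$alt_mid_m, grid$alt_mid); m <- match(df$month, months)
  if (any(is.na(i) | is.na(j) | is.na(k) | is.na(m))) {
    stop("dust grid file coordinates do not match the supplied grid",
         call. = FALSE)
  }
  dext[cbind(i, j, k, m)] <- df$dext_Mm
  nsamp[cbind(i, j, m)] <- df$n_samples
  new_dust_grid(grid, months, dext, nsamp)
}

#' Write / read regional series CSV
#'
#' Columns `region` (optional on write if absent), `year`, `variable`,
#' `value`.
#'
#' @param series Tibble/data.frame of series.
#' @param path CSV file.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_series_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- read.csv(path)
  need <- c("year", "variable", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("series file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

# Known pipeline-config keys, with defaults applied in read_pipeline_config.
.config_defaults <- function() list(
  seed = 1L,
  grid = list(lon_min = 30, lon_max = 76, lat_min = 0, lat_max = 40,
              cell_deg = 2, alt_top_m = 7000, alt_bin_m = 1000),
  retrieval = list(delta_dust = 0.25, delta_nondust = 0.045,
                   lidar_ratio_dust = 44, cad_min = -100, cad_max = -90),
  flux = list(dmee = 0.37, z_top = 7000),
  granule = list(n_profiles = 200, noise_sd_rel = 0.05,
                 cad_outlier_fraction = 0.1),
  plume = list(kind = "uniform_advection", u0 = 8, v0 = 0, c0 = 1e-4,
               decay_length_deg = 15, plume_top_m = 3000),
  series = list(n_years = 14, start_year = 2007, cross_corr = 0.7,
                noise_sd = 1),
  sensitivity = list(dmee_values = c(0.37, 0.5),
                     lidar_ratio_values = c(30, 60))
)

#' Read and validate a pipeline configuration
#'
#' YAML configuration with sections `grid`, `retrieval`, `flux`,
#' `granule`, `plume`, `series`, `sensitivity` and a top-level `seed`.
#' Unknown keys (top-level or within a section) are rejected before any
#' stage runs; omitted keys take package defaults.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return A validated config list with attribute `"config_hash"`.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- .config_defaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(bad)) {
        stop("unknown config key(s) in `", sec, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      defaults[[sec]] <- modifyList(defaults[[sec]], cfg[[sec]])
    } else defaults[[sec]] <- cfg[[sec]]
  }
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(defaults, tmp)
  attr(defaults, "config_hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  defaults
}
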