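#' Run the full synthetic-data pipeline
#'
#' Orchestrates every stage on synthetic inputs generated from the
#' config seed: (1) simulate a lidar granule, a plume scenario with
#' known deposition, and correlated regional series; (2) screen,
#' partition and grid the granule; (3) build mass fluxes and (4)
#' deposition, loss frequency and lifetime from the plume-derived
#' extinction and winds, comparing the recovered total deposition
#' against the scenario truth; (5) regional report (climatology, anomaly
#' trends, correlations); (6) DMEE and lidar-ratio sensitivity sweeps.
#' All numerics live in the stage functions; this wrapper only wires
#' them together, writes the output files and records provenance (config
#' hash, package version, seed) in the JSON report.
#'
#' @param config A config list from [read_pipeline_config()] (or `NULL`
#'   for defaults).
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @return Invisibly, a list bundle with every stage product.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.null(config)) config <- read_pipeline_config(NULL)
  cfg <- config
  grid <- grid_def(cfg$grid$lon_min, cfg$grid$lon_max,
                   cfg$grid$lat_min, cfg$grid$lat_max,
                   cell_deg = cfg$grid$cell_deg,
                   alt_edges = seq(0, cfg$grid$alt_top_m,
                                   by = cfg$grid$alt_bin_m))
  rparams <- retrieval_params(cfg$retrieval$delta_dust,
                              cfg$retrieval$delta_nondust,
                              cfg$retrieval$lidar_ratio_dust,
                              c(cfg$retrieval$cad_min, cfg$retrieval$cad_max))

  # --- simulate -----------------------------------------------------------
  gspec <- granule_spec(
    n_profiles = cfg$granule$n_profiles,
    lat_range = c(cfg$grid$lat_min, cfg$grid$lat_max),
    lon_range = c(cfg$grid$lon_min, cfg$grid$lon_max),
    cad_outlier_fraction = cfg$granule$cad_outlier_fraction,
    noise_sd_rel = cfg$granule$noise_sd_rel,
    seed = cfg$seed)
  granule <- make_granule(gspec)
  plume <- make_plume(cfg$plume$kind, grid,
                      u0 = cfg$plume$u0, v0 = cfg$plume$v0,
                      c0 = cfg$plume$c0,
                      decay_length_deg = cfg$plume$decay_length_deg,
                      plume_top_m = cfg$plume$plume_top_m)
  sspec <- series_spec(n_years = cfg$series$n_years,
                       start_year = cfg$series$start_year,
                       cross_corr = cfg$series$cross_corr,
                       noise_sd = cfg$series$noise_sd,
                       seed = cfg$seed + 1L)
  regions <- names(default_regions())
  series <- do.call(rbind, lapply(seq_along(regions), function(k) {
    s <- make_series(series_spec(
      n_years = cfg$series$n_years, start_year = cfg$series$start_year,
      slopes = sspec$slopes, noise_sd = cfg$series$noise_sd,
      cross_corr = cfg$series$cross_corr, seed = cfg$seed + k))
    s$region <- regions[k]
    s
  }))

  # --- retrieve -----------------------------------------------------------
  dust_grid <- grid_monthly(
    partition_profiles(screen_profiles(granule, rparams), rparams), grid)

  # --- flux + deposition on the plume oracle ------------------------------
  inputs <- plume_to_inputs(plume, dmee = cfg$flux$dmee)
  fparams <- flux_params(dmee = cfg$flux$dmee, z_top = cfg$flux$z_top)
  flux <- flux_profiles(inputs$dust_grid, inputs$winds, fparams)
  dep <- divergence_deposition(flux)
  dlf <- loss_frequency(dep$ddf_area[, , 1], flux$loading[, , 1])
  dlt <- dust_lifetime(dlf)
  oracle_err_pct <- 100 * abs(sum(dep$ddf[, , 1], na.rm = TRUE) -
                                plume$closure$total_truth) /
    plume$closure$total_truth

  # --- statistics ---------------------------------------------------------
  report <- region_report(series, focal = names(sspec$slopes)[1])

  # --- sensitivity --------------------------------------------------------
  sweep_dmee <- dmee_sweep(inputs$dust_grid, inputs$winds,
                           cfg$sensitivity$dmee_values,
                           z_top = cfg$flux$z_top)
  sweep_s <- lidar_ratio_sweep(granule, cfg$sensitivity$lidar_ratio_values,
                               grid, rparams)

  bundle <- list(
    config = cfg, grid = grid, granule = granule, plume = plume,
    series = tibble::as_tibble(series), dust_grid = dust_grid,
    flux = flux, deposition = dep, dlf = dlf, dlt = dlt,
    oracle_deposition_error_pct = oracle_err_pct,
    region_report = report,
    sweep_dmee = sweep_dmee, sweep_lidar_ratio = sweep_s
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_granule_csv(granule, file.path(out_dir, "granule.csv"))
    write_dust_grid_csv(dust_grid, file.path(out_dir, "dust_grid.csv"))
    write_series_csv(series, file.path(out_dir, "regional_series.csv"))
    write.csv(dep$totals, file.path(out_dir, "deposition_totals.csv"),
              row.names = FALSE)
    write.csv(report$climatology, file.path(out_dir, "climatology.csv"),
              row.names = FALSE)
    prov <- list(
      package = "dustflux",
      version = as.character(utils::packageVersion("dustflux")),
      seed = cfg$seed,
      config_hash = attr(cfg, "config_hash"))
    jsonlite::write_json(list(
      provenance = prov,
      oracle_deposition_error_pct = oracle_err_pct,
      deposition_totals = dep$totals,
      budget = dep$budget,
      trends = report$trends,
      correlations = report$correlations,
      sweep_dmee = sweep_dmee$pairwise,
      sweep_lidar_ratio = sweep_s$pairwise
    ), file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
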