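# Shared fixtures, built in code at test time.

GS_TO_TG <- 3.1536e-5  # 1 g/s in Tg/yr (365-day year)

# A small clean granule: one dust layer over background, no noise.
clean_granule <- function(n_profiles = 20, noise = 0, cad_out = 0,
                          seed = 42) {
  make_granule(granule_spec(
    n_profiles = n_profiles,
    lat_range = c(10, 20), lon_range = c(50, 70),
    altitude_grid = seq(0, 7000, by = 250),
    dust_layers = list(c(500, 3500, 0.1)),
    nondust_background = 0.02,
    cad_outlier_fraction = cad_out, noise_sd_rel = noise,
    seed = seed))
}

# Small grid for fast flux/deposition tests.
small_grid <- function(cell = 2) {
  grid_def(lon_min = 50, lon_max = 70, lat_min = 8, lat_max = 22,
           cell_deg = cell, alt_edges = seq(0, 4000, 1000))
}

# Uniform dust grid + winds on `grid`: dext chosen so DMC is `dmc` g/m^3
# at the given DMEE in every cell/bin.
uniform_inputs <- function(grid, dmc = 1e-5, u = 10, v = 0, dmee = 0.37,
                           month = "2007-07") {
  dext <- array(dmc * dmee * 1e6, c(grid$nlon, grid$nlat, grid$nalt, 1))
  dg <- dustflux:::new_dust_grid(grid, month, dext,
                                 array(1L, c(grid$nlon, grid$nlat, 1)))
  w <- wind_field(grid, month,
                  u = array(u, c(grid$nlon, grid$nlat, grid$nalt, 1)),
                  v = array(v, c(grid$nlon, grid$nlat, grid$nalt, 1)))
  list(dust_grid = dg, winds = w)
}
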