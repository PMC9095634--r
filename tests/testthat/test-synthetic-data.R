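test_that("granule generation honours the two-component limits", {
  # pure dust: no background, one layer -> in-layer dust fraction 1
  g_dust <- make_granule(granule_spec(
    n_profiles = 5, nondust_background = 0,
    dust_layers = list(c(500, 3500, 0.1)), seed = 1))
  in_layer <- g_dust$levels >= 500 & g_dust$levels <= 3500
  expect_true(all(g_dust$truth$dust_fraction[in_layer, ] == 1))
  expect_true(all(g_dust$truth$dust_fraction[!in_layer, ] == 0))
  expect_true(all(g_dust$pdr[in_layer, ] == 0.25))

  # no dust layers -> dust fraction 0 everywhere, PDR at non-dust endmember
  g_clean <- make_granule(granule_spec(
    n_profiles = 5, dust_layers = list(), seed = 1))
  expect_true(all(g_clean$truth$dust_fraction == 0))
  expect_true(all(g_clean$pdr == 0.045))
})

test_that("granule generation is seed-deterministic and validates its spec", {
  a <- make_granule(granule_spec(n_profiles = 30, noise_sd_rel = 0.1,
                                 cad_outlier_fraction = 0.2, seed = 7))
  b <- make_granule(granule_spec(n_profiles = 30, noise_sd_rel = 0.1,
                                 cad_outlier_fraction = 0.2, seed = 7))
  expect_identical(a, b)
  c <- make_granule(granule_spec(n_profiles = 30, noise_sd_rel = 0.1,
                                 cad_outlier_fraction = 0.2, seed = 8))
  expect_false(identical(a$beta_p, c$beta_p))

  expect_error(granule_spec(dust_layers = list(c(500, 3500, -0.1))),
               "extinction")
  expect_error(granule_spec(nondust_background = -1), ">= 0")
  expect_error(granule_spec(altitude_grid = numeric(0)), "altitude_grid")
  expect_error(granule_spec(delta_dust_true = 1.2), "PDR")
  expect_error(granule_spec(cad_outlier_fraction = 2), "cad_outlier")
})

test_that("composite PDR mixing inverts exactly under the retrieval partition", {
  # arbitrary endmember pair with delta_d > delta_nd
  for (pars in list(c(0.25, 0.045), c(0.31, 0.02), c(0.2, 0.07))) {
    p <- retrieval_params(delta_dust = pars[1], delta_nondust = pars[2])
    g <- make_granule(granule_spec(
      n_profiles = 3, delta_dust_true = pars[1], delta_nondust_true = pars[2],
      dust_layers = list(c(0, 2000, 0.05), c(3000, 5000, 0.2)),
      nondust_background = 0.03, seed = 3))
    f_hat <- dust_fraction(g$pdr, p)
    expect_lt(max(abs(f_hat - g$truth$dust_fraction)), 1e-10)
  }
})

test_that("plume scenarios close their mass budget exactly", {
  for (kind in c("uniform_advection", "gaussian_plume")) {
    pl <- make_plume(kind, small_grid(), u0 = 8, v0 = 2)
    gap <- pl$closure$total_truth -
      (pl$closure$boundary_in - pl$closure$boundary_out)
    expect_lt(abs(gap), 1e-6 * max(abs(pl$closure$total_truth), 1))
  }
})

test_that("uniform concentration in uniform wind deposits nothing", {
  pl <- make_plume("uniform_advection", small_grid(), u0 = 8,
                   decay_length_deg = 1e12)
  expect_lt(max(abs(pl$truth_deposition)) /
              (pl$params$u0 * pl$params$c0 * pl$depth_m * 1e5), 1e-10)
})

test_that("1-D plume truth matches the analytic face-difference form", {
  g <- small_grid()
  pl <- make_plume("uniform_advection", g, u0 = 8, v0 = 0, c0 = 1e-4,
                   decay_length_deg = 15, plume_top_m = 3000)
  # truth per cell = -u0 * (C(east) - C(west)) * face_length * depth
  Lm <- g$earth_radius * pi / 180 * g$cell_deg
  cfun <- function(lon) 1e-4 * exp(-(lon - g$lon_edges[1]) / 15)
  for (i in c(1, 4, g$nlon)) {
    expected <- -8 * (cfun(g$lon_edges[i + 1]) - cfun(g$lon_edges[i])) *
      Lm * 3000
    expect_equal(pl$truth_deposition[i, 1], expected, tolerance = 1e-12)
  }
  # and agrees with central finite differences on a 10x finer grid
  fine <- seq(g$lon_edges[1], g$lon_edges[2], length.out = 11)
  fd <- -8 * 3000 * Lm * sum(diff(cfun(fine)))
  expect_equal(pl$truth_deposition[1, 1], fd, tolerance = 1e-9)
})

test_that("reversing the wind mirrors the gaussian plume deposition", {
  g <- small_grid()
  east <- make_plume("gaussian_plume", g, u0 = 5, v0 = 0, sigma_deg = 4)
  west <- make_plume("gaussian_plume", g, u0 = -5, v0 = 0, sigma_deg = 4)
  # deposition pattern mirrors in lon (deposition moves to the new
  # downwind side; signs are preserved, not flipped)
  expect_equal(west$truth_deposition,
               east$truth_deposition[g$nlon:1, ], tolerance = 1e-12)
})

test_that("series generator recovers prescribed trends and correlations", {
  # noiseless: fitted slope is exactly the prescribed one
  s <- make_series(series_spec(slopes = c(DDF = -5.8), noise_sd = 0,
                               cross_corr = 0, seed = 1))
  expect_equal(trend_slope(s$year, s$value)$slope, -5.8, tolerance = 1e-12)

  # perfect correlation, equal slopes -> r = 1
  s2 <- make_series(series_spec(slopes = c(a = 1, b = 1), noise_sd = 1,
                                cross_corr = 1, seed = 2))
  a <- s2$value[s2$variable == "a"]; b <- s2$value[s2$variable == "b"]
  expect_equal(cor(a, b), 1, tolerance = 1e-9)

  # factor construction hits the target correlation at large n
  s3 <- make_series(series_spec(n_years = 1e4, slopes = c(x = 0, y = 0),
                                noise_sd = 1, cross_corr = 0.73, seed = 3))
  x <- s3$value[s3$variable == "x"]; y <- s3$value[s3$variable == "y"]
  expect_lt(abs(cor(x, y) - 0.73), 0.02)

  expect_error(series_spec(cross_corr = 1.5), "cross_corr")
  expect_error(series_spec(n_years = 2), "n_years")
  expect_identical(make_series(series_spec(seed = 9)),
                   make_series(series_spec(seed = 9)))
})
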