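run_plume_deposition <- function(cell_deg, kind = "uniform_advection", ...) {
  g <- grid_def(50, 70, 8, 22, cell_deg = cell_deg,
                alt_edges = seq(0, 4000, 1000))
  pl <- make_plume(kind, g, ...)
  inp <- plume_to_inputs(pl)
  dep <- divergence_deposition(flux_profiles(inp$dust_grid, inp$winds))
  list(plume = pl, dep = dep)
}

test_that("flux-divergence deposition recovers the analytic plume within 2%", {
  errs <- vapply(c(2, 1, 0.5), function(cd) {
    r <- run_plume_deposition(cd, u0 = 8, decay_length_deg = 15)
    expect_equal(sum(r$dep$negative_flag), 0)  # monotone decay: no clipping
    100 * abs(sum(r$dep$ddf[, , 1]) - r$plume$closure$total_truth) /
      r$plume$closure$total_truth
  }, numeric(1))
  expect_lt(errs[1], 2)
  expect_true(all(diff(errs) < 0))   # monotone convergence 2 -> 1 -> 0.5 deg
})

test_that("domain-total raw deposition telescopes to boundary in minus out", {
  r <- run_plume_deposition(2, kind = "gaussian_plume", u0 = 6, v0 = 3,
                            sigma_deg = 5)
  est_in_out <- r$dep$budget$boundary_in - r$dep$budget$boundary_out
  expect_equal(sum(r$dep$raw[, , 1]), est_in_out, tolerance = 1e-12)
})

test_that("divergence-free flow deposits nothing anywhere", {
  # uniform zonal flux is divergence-free on the sphere (meridional faces
  # all have equal length); a uniform meridional flux would not be
  inp <- uniform_inputs(small_grid(), dmc = 1e-5, u = 10, v = 0)
  dep <- divergence_deposition(flux_profiles(inp$dust_grid, inp$winds))
  expect_lt(max(abs(dep$raw)), 1e-6)
  # any flagged cells are pure floating-point residue, not real uptake
  expect_lt(max(abs(dep$raw[dep$negative_flag]), 0), 1e-6)
  expect_equal(dep$totals$total_clipped_Tg_yr, 0, tolerance = 1e-10)
})

test_that("a concentration step down the wind deposits at the step", {
  grid <- grid_def(50, 56, 10, 14, 2, alt_edges = c(0, 1000))
  dext <- array(NA_real_, c(3, 2, 1, 1))
  dext[1, , 1, 1] <- 37; dext[2, , 1, 1] <- 37; dext[3, , 1, 1] <- 18.5
  dg <- dustflux:::new_dust_grid(grid, "2007-07", dext,
                                 array(1L, c(3, 2, 1)))
  w <- wind_field(grid, "2007-07", u = array(10, c(3, 2, 1, 1)),
                  v = array(0, c(3, 2, 1, 1)))
  dep <- divergence_deposition(flux_profiles(dg, w))
  # hand calculation per lat row: column fluxes F = (1,1,0.5) g/m/s
  # faces: west 1.5*1-0.5*1=1; 1; 0.75; east 1.5*0.5-0.5*1=0.25
  # raw/Lm: cell1 = 0, cell2 = 0.25, cell3 = 0.5
  Lm <- grid$earth_radius * pi / 180 * 2
  expect_equal(unname(dep$raw[, 1, 1]) / Lm, c(0, 0.25, 0.5),
               tolerance = 1e-12)
  expect_true(all(dep$ddf >= 0))
})

test_that("negative divergence is flagged, excluded from totals, kept raw", {
  r <- run_plume_deposition(2, kind = "gaussian_plume", u0 = 6,
                            sigma_deg = 5)
  dep <- r$dep
  expect_gt(sum(dep$negative_flag), 0)         # uptake side exists
  expect_true(all(dep$ddf[dep$negative_flag] == 0))
  expect_true(all(dep$raw[dep$negative_flag] < 0))
  tot <- dep$totals
  expect_gt(tot$total_clipped_Tg_yr, tot$total_net_Tg_yr)
})

test_that("land cells under the ocean mask carry no deposition", {
  grid <- small_grid()
  inp <- uniform_inputs(grid, dmc = 1e-5, u = 10)
  mask <- matrix(TRUE, grid$nlon, grid$nlat); mask[1:2, ] <- FALSE
  dep <- divergence_deposition(flux_profiles(inp$dust_grid, inp$winds), mask)
  expect_true(all(is.na(dep$ddf[1:2, , ])))
  expect_error(divergence_deposition(
    flux_profiles(uniform_inputs(grid_def(50, 52, 10, 12, 2,
                                          c(0, 1000)))$dust_grid,
                  uniform_inputs(grid_def(50, 52, 10, 12, 2,
                                          c(0, 1000)))$winds)),
    "at least 2 cells")
})

test_that("loss frequency and lifetime obey their definitions", {
  expect_equal(loss_frequency(0.5, 1), 0.5)
  expect_equal(dust_lifetime(0.5), 2)
  expect_equal(dust_lifetime(2.5), 0.4)
  expect_equal(loss_frequency(0, 1), 0)
  expect_true(is.na(dust_lifetime(0)))
  expect_true(is.na(dust_lifetime(NA_real_)))
  expect_warning(out <- loss_frequency(0.5, 0), "no loading")
  expect_true(is.na(out))
  # DLT * DLF = 1 wherever defined
  dlf <- c(0.1, 0.5, 2.5, 7)
  expect_equal(dust_lifetime(dlf) * dlf, rep(1, 4))
})

test_that("loss frequency is invariant to the assumed DMEE", {
  pl <- make_plume("uniform_advection", small_grid(), u0 = 8)
  dlf_at <- function(dmee) {
    inp <- plume_to_inputs(pl, dmee = dmee)
    ff <- flux_profiles(inp$dust_grid, inp$winds, flux_params(dmee = dmee))
    dep <- divergence_deposition(ff)
    loss_frequency(dep$ddf_area[, , 1], ff$loading[, , 1])
  }
  a <- dlf_at(0.37); b <- dlf_at(0.74)
  expect_equal(a, b, tolerance = 1e-12)
  # while DDF itself scales as 1/DMEE
  dep1 <- divergence_deposition(flux_profiles(
    plume_to_inputs(pl, 0.37)$dust_grid, plume_to_inputs(pl, 0.37)$winds,
    flux_params(dmee = 0.37)))
  dep2 <- divergence_deposition(flux_profiles(
    plume_to_inputs(pl, 0.37)$dust_grid, plume_to_inputs(pl, 0.37)$winds,
    flux_params(dmee = 0.74)))
  expect_equal(dep1$ddf, 2 * dep2$ddf, tolerance = 1e-12)
})

test_that("seasonal aggregation averages season-years with dispersion", {
  months <- sprintf("%d-%02d", rep(2007:2008, each = 12), rep(1:12, 2))
  x <- array(0, c(2, 2, 24))
  jja <- dustflux:::season_of(months) == "JJA"
  x[, , jja] <- 5                      # identical JJA months -> sd 0
  agg <- seasonal_aggregate(x, months, "JJA")
  expect_equal(agg$mean, matrix(5, 2, 2))
  expect_equal(agg$sd, matrix(0, 2, 2))
  expect_equal(agg$n_years, 2)

  # two-year cycle with known amplitude recovered exactly
  x2 <- array(0, c(1, 1, 24))
  x2[1, 1, jja] <- rep(c(2, 8), each = 3)   # JJA mean 2 in 2007, 8 in 2008
  agg2 <- seasonal_aggregate(x2, months, "JJA")
  expect_equal(agg2$mean[1, 1], 5)
  expect_equal(agg2$sd[1, 1], sd(c(2, 8)))

  # vector (domain-total) input, missing month reported in coverage
  v <- rep(1, 24); v[jja][1] <- NA
  aggv <- seasonal_aggregate(ifelse(seq_len(24) %in% which(jja)[-1], 1,
                                    NA), months, "JJA")
  expect_equal(aggv$mean, 1)
  expect_error(seasonal_aggregate(x, months, "XXX"), "unknown season")

  # December joins the following winter
  expect_equal(dustflux:::season_year(c("2007-12", "2008-01")),
               c(2008L, 2008L))
})
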