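test_that("CAD screening keeps the confident-aerosol window and counts removals", {
  g <- clean_granule(n_profiles = 10)
  g$cad[] <- -95
  s <- screen_profiles(g)
  expect_identical(s$beta_p, g$beta_p)   # fully retained
  expect_equal(attr(s, "screening")$n_profiles_kept, 10)

  g$cad[] <- -50
  expect_warning(s2 <- screen_profiles(g), "removed every level")
  expect_true(all(is.na(s2$beta_p)))

  # window is closed: both endpoints retained
  g$cad[] <- -100; expect_equal(attr(screen_profiles(g), "screening")$n_levels_kept,
                                length(g$cad))
  g$cad[] <- -90;  expect_equal(attr(screen_profiles(g), "screening")$n_levels_kept,
                                length(g$cad))

  # generator bookkeeping: 20% outliers of 100 profiles -> 80 kept
  g3 <- clean_granule(n_profiles = 100, cad_out = 0.2)
  s3 <- screen_profiles(g3)
  expect_equal(attr(s3, "screening")$n_profiles_kept, 80)
  expect_equal(sum(g3$truth$is_cad_outlier), 20)
})

test_that("dust fraction matches the two-component partition formula", {
  expect_equal(dust_fraction(0.25), 1)        # dust endmember
  expect_equal(dust_fraction(0.045), 0)       # non-dust endmember
  expect_equal(dust_fraction(0.14), 0.5081, tolerance = 1e-4)
  # brute-force inversion oracle: mix known fractions, re-partition
  f_true <- seq(0, 1, by = 0.05)
  beta <- 1e-3
  pdr_mix <- dustflux:::mix_pdr(f_true * beta, (1 - f_true) * beta,
                                0.25, 0.045)
  expect_equal(dust_fraction(pdr_mix), f_true, tolerance = 1e-12)
  # clipped outside the endmember range
  expect_equal(dust_fraction(c(0.01, 0.6)), c(0, 1))
  # monotone nondecreasing in PDR
  f <- dust_fraction(seq(0, 0.8, by = 0.01))
  expect_true(all(diff(f) >= 0))
  expect_error(retrieval_params(delta_dust = 0.04, delta_nondust = 0.045),
               "delta_dust > delta_nondust")
})

test_that("dust extinction is backscatter times lidar ratio, with round trip", {
  expect_equal(dust_extinction(0.001, 44), 0.044)
  expect_equal(dust_extinction(0), 0)
  expect_error(dust_extinction(-1), ">= 0")

  # zero-noise granule: partition recovers the prescribed dust extinction
  g <- clean_granule()
  pg <- partition_profiles(screen_profiles(g))
  nonzero <- g$truth$alpha_dust > 0
  rel <- abs(pg$dext[nonzero] - g$truth$alpha_dust[nonzero]) /
    g$truth$alpha_dust[nonzero]
  expect_lt(max(rel), 1e-10)
})

test_that("column optical depth integrates extinction correctly", {
  # uniform 0.1 /km over 0-2 km -> 0.2
  expect_equal(column_dod(rep(0.1, 5), seq(0, 2000, by = 500)), 0.2)
  # all-missing -> missing; < 2 valid levels -> missing
  expect_true(is.na(column_dod(rep(NA_real_, 5), seq(0, 2000, 500))))
  expect_true(is.na(column_dod(c(0.1, NA, NA), c(0, 500, 1000))))
  # ceiling honoured
  expect_equal(column_dod(rep(0.1, 11), seq(0, 10000, 1000), z_top = 7000),
               0.7)
  # gaussian layer vs closed-form erf integral, 60 m spacing
  z <- seq(0, 7000, by = 60); z0 <- 3000; s <- 600; a <- 0.2
  dext <- a * exp(-(z - z0)^2 / (2 * s^2))
  closed <- a * (s / 1000) * sqrt(2 * pi) *
    (pnorm((7000 - z0) / s) - pnorm((0 - z0) / s))
  expect_equal(column_dod(dext, z), closed, tolerance = 0.005)
})

test_that("monthly gridding averages per cell and never backfills zeros", {
  grid <- small_grid()
  # two identical profiles in one cell -> mean equals either profile
  g <- make_granule(granule_spec(
    n_profiles = 2, lat_range = c(10.1, 11.9), lon_range = c(50.1, 51.9),
    altitude_grid = seq(0, 4000, 250), dust_layers = list(c(0, 4000, 0.1)),
    nondust_background = 0, seed = 5))
  dg <- grid_monthly(partition_profiles(screen_profiles(g)), grid)
  expect_equal(dg$n_samples[1, 2, 1], 2L)  # cell (50-52E, 10-12N)
  expect_equal(unname(dg$dext[1, 2, , 1]), rep(100, grid$nalt))  # 0.1/km = 100/Mm
  # all other cells missing, not zero
  expect_true(all(is.na(dg$dext[2:grid$nlon, , , 1])))
  # dod = vertical integral of binned dext
  expect_equal(dg$dod[1, 2, 1], sum(100 * 1e-6 * grid$dz))

  # profiles outside the grid are dropped with a count
  g_out <- make_granule(granule_spec(
    n_profiles = 4, lat_range = c(80, 85), lon_range = c(50, 52),
    altitude_grid = seq(0, 4000, 250), seed = 6))
  dg2 <- grid_monthly(partition_profiles(screen_profiles(g_out)), grid)
  expect_equal(attr(dg2, "n_dropped"), 4)
  expect_true(all(dg2$n_samples == 0))
})

test_that("noisy cell means land within 3 standard errors of the truth", {
  grid <- small_grid()
  g <- make_granule(granule_spec(
    n_profiles = 200, lat_range = c(10.1, 11.9), lon_range = c(50.1, 51.9),
    altitude_grid = seq(0, 4000, 250), dust_layers = list(c(0, 4000, 0.1)),
    nondust_background = 0.02, noise_sd_rel = 0.1, seed = 11))
  pg <- partition_profiles(screen_profiles(g))
  dg <- grid_monthly(pg, grid)
  truth_bin <- mean(g$truth$alpha_dust[, 1]) * 1e3   # uniform layer, Mm^-1
  for (b in seq_len(grid$nalt)) {
    cellmean <- dg$dext[1, 2, b, 1]
    se <- sd(pg$dext[1, ] * 1e3) / sqrt(200)   # same-order noise per level
    expect_lt(abs(cellmean - truth_bin), 3 * se + 0.05 * truth_bin)
  }
})

test_that("gridded DOD equals the mean of per-profile DODs for shared full columns", {
  grid <- small_grid()
  g <- make_granule(granule_spec(
    n_profiles = 50, lat_range = c(10.1, 11.9), lon_range = c(50.1, 51.9),
    altitude_grid = seq(125, 3875, 250),  # level centres of the 1 km bins
    dust_layers = list(c(0, 4000, 0.08)), nondust_background = 0.02,
    noise_sd_rel = 0.2, seed = 12))
  pg <- partition_profiles(screen_profiles(g))
  dg <- grid_monthly(pg, grid)
  # rectangle-rule per-profile DOD on the same bins
  prof_dod <- colSums(pg$dext) * 0.25   # km^-1 times 0.25 km spacing
  expect_equal(dg$dod[1, 2, 1], mean(prof_dod), tolerance = 1e-10)
})
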