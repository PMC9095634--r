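# dustflux

Satellite-style quantification of mineral dust transport and deposition
over an ocean basin, and of its association with ocean productivity.

Mineral dust blown off arid coasts is a major source of nutrients (iron,
phosphorus, nitrate-associated inputs) to oligotrophic seas such as the
Arabian Sea. Spaceborne polarization lidar can see where that dust is —
dust particles are non-spherical, so they depolarize the backscattered
laser light — but turning lidar profiles into *deposition* requires a
chain of physical conversions. `dustflux` implements that chain as a
tested R pipeline, for researchers in aerosol remote sensing and ocean
biogeochemistry who want the method itself, runnable and verifiable on
synthetic data with known answers, independent of any satellite archive.

## The method

Starting from screened nighttime aerosol profiles (cloud–aerosol
discrimination score within `[-100, -90]`), five steps per calendar month
on a 2° × 2° grid:

1. **Partition** the particulate backscatter β_p at 532 nm into dust and
   non-dust with the two-component particulate depolarization ratio (PDR)
   method. For endmembers δ_d (dust, default 0.25) and δ_nd (non-dust,
   default 0.045), an observed composite PDR δ implies a dust backscatter
   fraction

       f_d = (δ − δ_nd)(1 + δ_d) / ((δ_d − δ_nd)(1 + δ)),  clipped to [0, 1].

   Dust extinction follows as DExt = f_d · β_p · S with the characteristic
   dust lidar ratio S = 44 sr; its column integral is the dust optical
   depth (DOD).
2. **Mass concentration**: DMC = DExt / DMEE, with dust mass extinction
   efficiency DMEE = 0.37 m² g⁻¹ (assumed height- and humidity-independent).
3. **Mass flux**: DMF profiles = DMC × monthly wind profiles (u, v),
   per 1 km altitude bin, column-integrated from the surface to 7 km
   (dust above 7 km is negligible).
4. **Deposition** by the flux-divergence method: with no leak through the
   tropopause and no ocean surface source, the deposition flux DDF into a
   cell is the net convergence of the column-integrated fluxes through its
   four faces. Cells with negative raw divergence are flagged as
   non-physical and excluded from totals.
5. **Loss frequency and lifetime**: DLF = DDF (g m⁻² day⁻¹) / column mass
   loading (g m⁻², = DOD/DMEE) — the DMEE cancels — and DLT = 1/DLF.

On top sit the statistics used to interpret the fields: per-cell OLS
trends with Mann–Kendall significance tiers (90/95/99%), climatological
anomalies, area-weighted regional means (western/central/eastern basin
sectors), Pearson correlations between deposition, net primary
productivity (NPP) and nitrate series, and sensitivity sweeps over DMEE
and the dust lidar ratio.

Every stage is testable without downloads through the synthetic module:
`make_granule()` (two-component mixtures with known dust fractions),
`make_plume()` (advected plumes whose deposition is known analytically,
with exact mass closure), and `make_series()` (regional series with
prescribed trends and cross-correlations).

## Worked example

```r
library(dustflux)

# synthetic granule: dust layer 0.5-3.5 km over marine background,
# 5% noise, 10% cloud-contaminated profiles
g <- make_granule(granule_spec(n_profiles = 200, noise_sd_rel = 0.05,
                               cad_outlier_fraction = 0.1, seed = 42))
params <- retrieval_params()          # PDR 0.25/0.045, S = 44 sr
g  <- screen_profiles(g, params)
attr(g, "screening")$n_profiles_kept
#> [1] 180                            # the 10% CAD outliers are gone
dg <- grid_monthly(partition_profiles(g, params), grid_def())
dg
#> <dust_grid> 23x20x7 cells x 1 month(s); mean DOD 0.3012 (49 sampled cells)

# plume with analytically known deposition, through flux + divergence
plume <- make_plume("uniform_advection", grid_def(), u0 = 8)
inp   <- plume_to_inputs(plume, dmee = 0.37)
flux  <- flux_profiles(inp$dust_grid, inp$winds, flux_params())
dep   <- divergence_deposition(flux)
dep$totals$total_clipped_Tg_yr
#> [1] 319.0177                       # truth: 320.9585 Tg/yr (error 0.6%)

# loss frequency -> lifetime (days)
dlf <- loss_frequency(dep$ddf_area[, , 1], flux$loading[, , 1])
summary(as.vector(dust_lifetime(dlf)))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.753   2.073   2.246   2.216   2.376   2.577

# dust import through the western boundary, Tg/yr
tw <- transect("west", "meridional", at = 50, span = c(8, 22))
transect_flux(flux, tw)$total_Tg_yr
#> [1] 31.1269

# regional anomaly trends and NPP-DDF correlation on a synthetic record
s <- make_series(series_spec(n_years = 14, slopes = c(NPP = -5.8, DDF = -0.2),
                             noise_sd = 1, cross_corr = 0.73, seed = 1))
s$region <- "WAS"
rep <- region_report(s, focal = "NPP")
rep$trends
#>   region variable  slope           p tier      n
#> 1 WAS    NPP      -5.88  0.000000835 99       14
#> 2 WAS    DDF      -0.323 0.000688    99       14
rep$correlations
#>   region var_x var_y     r        p     n
#> 1 WAS    NPP   DDF   0.833 0.000219    14
```

The deposition total is the domain sum of per-cell convergence of the
plume's column flux; its agreement with the prescribed sink (0.6% at 2°,
improving under grid refinement) is the core correctness check of the
flux-divergence estimator. The lifetime of ~2 days reflects the ratio of
the plume's loading to its deposition rate. The recovered trend slopes
match the prescribed ones up to the added noise, and the correlation
recovers the prescribed ρ = 0.73 at the precision a 14-year sample
allows.

A full orchestrated run (`run_pipeline()`, or
`Rscript scripts/dustflux.R run --seed 1 --out-dir out/`) writes the
granule, gridded product, deposition totals, regional report and
sensitivity sweeps as CSV/JSON with provenance (seed, config hash,
package version).

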