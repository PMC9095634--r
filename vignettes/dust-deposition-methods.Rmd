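---
title: "Methods: depolarization-based dust quantification and flux-divergence deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depolarization-based dust quantification and flux-divergence deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustflux)
```

## The physical model

`dustflux` estimates how much mineral dust an ocean basin receives from
the atmosphere, using only quantities a polarization lidar (plus a wind
reanalysis) can provide. The chain is:

**Partition.** Dust is non-spherical and depolarizes backscattered
light; marine and other fine aerosol barely does. Treating each range
bin as a two-component external mixture of a dust endmember with
particulate depolarization ratio (PDR) $\delta_d$ and a non-dust
endmember with $\delta_{nd}$, the dust share of particulate backscatter
implied by an observed composite PDR $\delta$ is

$$ f_d \;=\; \frac{(\delta - \delta_{nd})\,(1 + \delta_d)}
                 {(\delta_d - \delta_{nd})\,(1 + \delta)}, $$

clipped to $[0,1]$. The form follows from the fact that depolarization
mixes through the co-polarized backscatter $\beta/(1+\delta)$, not
through $\beta$ itself. Observations between the endmembers ("mixed
dust") are partitioned continuously by the same formula; values at or
beyond an endmember saturate at 0 or 1. The synthetic granule generator
uses the exact algebraic inverse of this formula as its mixing rule, so
at zero noise the partition recovers the generator's per-level dust
fraction to machine precision — a round trip the test suite asserts at
$10^{-10}$.

**Extinction and optical depth.** Dust extinction is
$\alpha_d = f_d\,\beta_p\,S_d$ with a characteristic dust lidar ratio
$S_d$; the column integral of $\alpha_d$ (trapezoidal over valid levels,
surface to the 7 km ceiling) is the dust optical depth (DOD).

**Mass.** Extinction converts to mass concentration through the dust
mass extinction efficiency: $\mathrm{DMC} = \alpha_d / \mathrm{DMEE}$,
with DMEE treated as a single scalar, independent of altitude and
humidity. Column mass loading is $\mathrm{DOD}/\mathrm{DMEE}$.

**Flux.** Per altitude bin, flux density is DMC times the co-registered
monthly wind component; layer flux is density times bin thickness;
column flux (g m$^{-1}$ s$^{-1}$) sums bins with midpoints below the
ceiling.

**Deposition by flux divergence.** Assuming no leak through the top of
the column and no surface dust source over ocean, mass balance makes the
deposition into a cell the net convergence of column-integrated
horizontal fluxes through its faces. Cells where the raw divergence is
negative (apparent mass production) are flagged, reported, and excluded
from totals: they arise from discretization, sub-monthly wind–dust
covariance, and neglected processes, not from physics. Because clipping
is positively homogeneous, deposition still scales exactly as
$1/\mathrm{DMEE}$.

**Loss frequency and lifetime.** DLF is area-normalized deposition
(g m$^{-2}$ day$^{-1}$) divided by loading (g m$^{-2}$); DMEE cancels in
the ratio, making DLF the most robust quantity in the chain. DLT = 1/DLF
where DLF > 0; cells with zero deposition get missing lifetime rather
than infinity.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `delta_dust` | 0.25 | – | dust endmember PDR; midpoint of the typical dust range 0.2–0.3 |
| `delta_nondust` | 0.045 | – | non-dust endmember PDR; midpoint of 0.02–0.07 |
| `lidar_ratio_dust` | 44 | sr | dust extinction-to-backscatter ratio (regional values span ~30–60 sr; the sensitivity sweep quantifies the impact) |
| `cad_window` | [−100, −90] | – | closed acceptance window of the cloud–aerosol discrimination score; keeps only confident-aerosol records |
| `dmee` | 0.37 | m² g⁻¹ | dust mass extinction efficiency; the sweep covers the 0.5 m² g⁻¹ alternative |
| `z_top` | 7000 | m | column ceiling; dust transport above 7 km is negligible over this basin |
| `cell_deg` | 2 | ° | analysis cell size; matches the sparse cross-track sampling of a single-footprint lidar |
| alt bins | 0–7 km by 1 km | m | vertical bins of the gridded product |

Defaults are set once, at the study conditions the method is designed
for; they are arguments, not constants, and every stage re-validates
them (`delta_dust > delta_nondust`, positive DMEE, etc.).

## What the synthetic generators emulate — and what they do not

`make_granule()` emulates the *structure* of a screened nighttime
level-2 aerosol profile product: 60 m level spacing to 10 km, per-level
backscatter/PDR/CAD, a prescribed fraction of cloud-contaminated
profiles (CAD outside the window), multiplicative log-normal noise on
backscatter and additive Gaussian noise on PDR (sd = `noise_sd_rel` ×
true PDR, clipped to [0, 0.8]). Because the generator needs both
endmember lidar ratios to build total backscatter from the prescribed
extinctions, it carries `lidar_ratio_dust_true = 44` sr and
`lidar_ratio_nondust = 25` sr (a standard marine value). It does **not**
emulate multiple scattering, daytime solar background, cloud layers,
aerosol typing beyond two components, or retrieval bias in β itself —
so passing tests demonstrate the correctness of the *processing chain*,
not of a lidar retrieval.

`make_plume()` provides the deposition oracle. Its truth field is built
from face integrals of the analytic column flux (fine midpoint
quadrature along every cell face), which makes the cell-by-cell truth
equal minus the divergence by construction and makes domain-total truth
equal boundary inflow minus outflow to machine precision. The
`uniform_advection` kind (exponential decay downwind under uniform wind)
yields strictly positive deposition everywhere — the clean benchmark;
the `gaussian_plume` kind produces an uptake (negative) side that
exercises the flagging logic.

`make_series()` builds interannual series as trend plus correlated
Gaussian noise, using the symmetric square root of the equicorrelation
matrix (valid over the whole PSD range including $\rho = 1$). Noiseless
specs recover slopes exactly; the sample correlation converges to the
target as years grow, which is why the recovery test uses $n = 10^4$.

## Numerical choices

- **Face-flux estimator.** Interior faces take the arithmetic mean of
  the two adjacent cell-centre column fluxes (second-order centred).
  Domain-edge faces use one-sided *linear extrapolation* from the two
  nearest cells, `1.5 F₁ − 0.5 F₂`: still one-sided, but second order,
  and — like any face-value scheme — it preserves the telescoping sum,
  so domain-total raw deposition equals boundary inflow minus outflow
  exactly. A first-order edge copy would already cost several percent of
  the domain total on smooth fields at 2°, dominating the interior
  error.
- **Geometry.** Spherical Earth, R = 6.371×10⁶ m. Meridional faces have
  length RΔφ (latitude-independent); zonal faces RΔλ cos φ. Cell areas
  use the exact spherical band formula. A consequence worth knowing:
  uniform *meridional* flux genuinely converges poleward (shrinking
  zonal faces); only uniform zonal flux is divergence-free.
- **Missing data.** Screened-out levels and empty cells are `NA`
  throughout, propagated through means and column sums (all-missing
  columns stay missing); nothing is backfilled with zeros. Deposition
  totals are reported in both bookkeepings: clipped (negatives as zero)
  and net (signed), so the effect of the exclusion rule is always
  visible.
- **Mann–Kendall.** Classic non-seasonal form: tie-corrected variance,
  ±1 continuity correction, two-sided normal-approximation p-values,
  tiers at p < 0.10/0.05/0.01 (90/95/99%). The normal approximation was
  chosen over exact tables because the annual records involved have
  n ≈ 14, where the approximation's 95%-tier type-I error is within one
  point of nominal (asserted by simulation in the tests). Trend slopes
  are OLS on the year index with the first year as base, because the
  trend definition in this methodology is a linear-regression slope;
  Sen's slope is available as an option.
- **CAD granularity.** Screening is applied per level (profile-level
  scores are broadcast to levels by the generator), since the profile
  product is level-resolved.
- **Sensitivity convention.** Percent differences are symmetric,
  relative to the pairwise mean: $200|A-B|/(A+B)$. Under pure
  $1/\mathrm{DMEE}$ scaling this is a pure function of the DMEE pair
  ({0.37, 0.5} → 29.9%), independent of the input fields; the sweep also
  emits first- and second-value-relative conventions for transparency,
  and reports the deviation from the closed form.
- **Regions.** Western/central/eastern sectors default to
  10–20°N with longitude splits 50–58/58–66/66–74°E — the latitude band
  is the heavy-deposition belt; the longitude splits are this package's
  own convention (the sector boundaries are not published as numbers)
  and are fully configurable. Regional means are cos(latitude)-weighted;
  splitting a region and recombining by weight reproduces the whole-region
  mean exactly. Variables with different record lengths (e.g. a nitrate
  record ending earlier) are matched on common years per pair.

## Problem sizes

The test suite and acceptance script run on: granules of 10–400 profiles
× ~40–170 levels; the 23 × 20-cell study grid (2°) with refinement
checks at 1° and 0.5°; Mann–Kendall null calibration on 10⁴ series of
length 14; correlation recovery on 10⁴-year synthetic series. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
tolerances while keeping a full run in minutes on one core.

## Known limitations

- The flux-divergence estimate cannot separate wet from dry deposition;
  it is the collective loss from all removal mechanisms.
- Monthly-mean winds × monthly-mean concentration ignores sub-monthly
  covariance between wind and dust.
- DMEE and the dust lidar ratio are single scalars; their regional
  variability is addressed only through the sensitivity sweeps.
- Negative-divergence cells are excluded, not corrected; where they
  cluster (plume uptake sides, strong gradients), clipped totals exceed
  net totals and both are reported.
- The 2° product inherits the sparse sampling of a single-track lidar:
  cells with no overpass in a month are missing, and regional statistics
  must tolerate that missingness.
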