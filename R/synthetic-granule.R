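#' Specification for a synthetic lidar granule
#'
#' Describes a batch of nighttime-quality aerosol profiles built as a
#' two-component (dust / non-dust) backscatter mixture with prescribed
#' endmember depolarization ratios. The generated granule carries the
#' per-level truth (dust backscatter fraction, dust extinction), so the
#' retrieval stage can be tested against a known answer.
#'
#' @param n_profiles Number of profiles.
#' @param lat_range,lon_range Length-2 numeric, degrees; profile footprints
#'   are drawn uniformly inside this box.
#' @param altitude_grid Strictly increasing altitudes in metres. The
#'   default mimics the 60 m vertical sampling of a spaceborne lidar
#'   level-2 profile product, surface to 10 km.
#' @param dust_layers List of `c(base_m, top_m, extinction_km1)` triplets:
#'   uniform dust extinction (per km) between base and top.
#' @param nondust_background Non-dust extinction (per km) applied at all
#'   levels.
#' @param delta_dust_true,delta_nondust_true Endmember particulate
#'   depolarization ratios (dimensionless, `0 <= delta < 1`).
#' @param lidar_ratio_dust_true,lidar_ratio_nondust Endmember
#'   extinction-to-backscatter ratios (sr) used to convert the prescribed
#'   extinctions to backscatter; 44 sr is the characteristic dust value,
#'   25 sr a typical marine aerosol value.
#' @param cad_outlier_fraction Fraction of profiles given cloud-aerosol
#'   discrimination (CAD) scores outside the confident-aerosol window
#'   `[-100, -90]`; these emulate cloud-contaminated records that the
#'   screening stage must drop.
#' @param noise_sd_rel Relative noise level: multiplicative log-normal
#'   noise on backscatter with log-sd `noise_sd_rel`, and additive
#'   Gaussian noise on the PDR with sd `noise_sd_rel * true PDR`, clipped
#'   to `[0, 0.8]`. Zero gives noiseless profiles.
#' @param months Character vector of `"YYYY-MM"` labels; profiles are
#'   assigned to months cyclically.
#' @param seed Integer seed; the same spec with the same seed yields a
#'   bit-identical granule.
#'
#' @return An object of class `granule_spec`.
#' @seealso [make_granule()]
#' @export
granule_spec <- function(n_profiles = 100,
                         lat_range = c(10, 20), lon_range = c(50, 70),
                         altitude_grid = seq(0, 10000, by = 60),
                         dust_layers = list(c(500, 3500, 0.1)),
                         nondust_background = 0.02,
                         delta_dust_true = 0.25,
                         delta_nondust_true = 0.045,
                         lidar_ratio_dust_true = 44,
                         lidar_ratio_nondust = 25,
                         cad_outlier_fraction = 0,
                         noise_sd_rel = 0,
                         months = "2007-07",
                         seed = 1L) {
  if (length(altitude_grid) < 1 || any(diff(altitude_grid) <= 0)) {
    stop("`altitude_grid` must be non-empty and strictly increasing",
         call. = FALSE)
  }
  if (nondust_background < 0) stop("extinctions must be >= 0", call. = FALSE)
  for (ly in dust_layers) {
    if (length(ly) != 3 || ly[3] < 0 || ly[2] <= ly[1]) {
      stop("each dust layer must be c(base_m, top_m, extinction_km1) with top > base and extinction >= 0",
           call. = FALSE)
    }
  }
  if (delta_dust_true < 0 || delta_dust_true >= 1 ||
      delta_nondust_true < 0 || delta_nondust_true >= 1) {
    stop("endmember PDRs must lie in [0, 1)", call. = FALSE)
  }
  if (cad_outlier_fraction < 0 || cad_outlier_fraction > 1) {
    stop("`cad_outlier_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_profiles = as.integer(n_profiles),
    lat_range = lat_range, lon_range = lon_range,
    altitude_grid = altitude_grid, dust_layers = dust_layers,
    nondust_background = nondust_background,
    delta_dust_true = delta_dust_true,
    delta_nondust_true = delta_nondust_true,
    lidar_ratio_dust_true = lidar_ratio_dust_true,
    lidar_ratio_nondust = lidar_ratio_nondust,
    cad_outlier_fraction = cad_outlier_fraction,
    noise_sd_rel = noise_sd_rel, months = months,
    seed = as.integer(seed)
  ), class = "granule_spec")
}

# Composite particulate depolarization ratio of a two-component mixture in
# backscatter space. Exact algebraic inverse of `dust_fraction()`.
mix_pdr <- function(beta_d, beta_nd, delta_d, delta_nd) {
  num <- beta_d * delta_d / (1 + delta_d) + beta_nd * delta_nd / (1 + delta_nd)
  den <- beta_d / (1 + delta_d) + beta_nd / (1 + delta_nd)
  out <- ifelse(den > 0, num / den, delta_nd)
  out
}

#' Generate a synthetic lidar granule
#'
#' Builds `n_profiles` altitude-resolved profiles of total particulate
#' backscatter at 532 nm, composite particulate depolarization ratio and
#' CAD score from the two-component mixture described by the spec, then
#' applies the spec's noise model. The truth (per-level dust backscatter
#' fraction and dust extinction, CAD-outlier flags) is attached under
#' `$truth` for testing; it is not part of the observable record.
#'
#' @param spec A [granule_spec()].
#' @return An object of class `lidar_granule`: list with `levels`
#'   (altitudes, m), per-profile vectors `lat`, `lon`, `month`, matrices
#'   `[n_levels x n_profiles]` `beta_p` (per km per sr), `pdr`, `cad`, and
#'   a `truth` list.
#' @examples
#' g <- make_granule(granule_spec(n_profiles = 10, seed = 7))
#' dim(g$beta_p)
#' @export
make_granule <- function(spec) {
  stopifnot(inherits(spec, "granule_spec"))
  z <- spec$altitude_grid
  nz <- length(z); np <- spec$n_profiles

  alpha_d <- numeric(nz)                      # dust extinction, km^-1
  for (ly in spec$dust_layers) {
    alpha_d[z >= ly[1] & z <= ly[2]] <- alpha_d[z >= ly[1] & z <= ly[2]] + ly[3]
  }
  alpha_nd <- rep(spec$nondust_background, nz)

  beta_d <- alpha_d / spec$lidar_ratio_dust_true   # km^-1 sr^-1
  beta_nd <- alpha_nd / spec$lidar_ratio_nondust
  beta_tot <- beta_d + beta_nd
  pdr_true <- mix_pdr(beta_d, beta_nd,
                      spec$delta_dust_true, spec$delta_nondust_true)
  frac_true <- ifelse(beta_tot > 0, beta_d / beta_tot, 0)

  with_seed(spec$seed, {
    lat <- runif(np, spec$lat_range[1], spec$lat_range[2])
    lon <- runif(np, spec$lon_range[1], spec$lon_range[2])
    n_out <- round(spec$cad_outlier_fraction * np)
    is_outlier <- rep(FALSE, np)
    if (n_out > 0) is_outlier[sample.int(np, n_out)] <- TRUE
    cad_prof <- ifelse(is_outlier, runif(np, -80, -20), runif(np, -100, -90))
    cad <- matrix(rep(cad_prof, each = nz), nz, np)

    beta_p <- matrix(rep(beta_tot, np), nz, np)
    pdr <- matrix(rep(pdr_true, np), nz, np)
    if (spec$noise_sd_rel > 0) {
      beta_p <- beta_p * exp(matrix(rnorm(nz * np, sd = spec$noise_sd_rel),
                                    nz, np))
      pdr <- pdr + matrix(rnorm(nz * np), nz, np) * spec$noise_sd_rel * pdr
      pdr <- pmin(pmax(pdr, 0), 0.8)
    }
    structure(list(
      levels = z, lat = lat, lon = lon,
      month = rep_len(spec$months, np),
      beta_p = beta_p, pdr = pdr, cad = cad,
      truth = list(dust_fraction = matrix(rep(frac_true, np), nz, np),
                   alpha_dust = matrix(rep(alpha_d, np), nz, np),
                   alpha_nondust = alpha_nd,
                   is_cad_outlier = is_outlier),
      spec = spec
    ), class = "lidar_granule")
  })
}

#' @export
print.lidar_granule <- function(x, ...) {
  cat(sprintf("<lidar_granule> %d profiles x %d levels (%g-%g m), months %s\n",
              length(x$lat), length(x$levels), min(x$levels), max(x$levels),
              paste(unique(x$month), collapse = ", ")))
  invisible(x)
}
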