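#' Retrieval parameters for the dust / non-dust partition
#'
#' Endmember particulate depolarization ratios (PDR), the characteristic
#' dust lidar ratio, and the cloud-aerosol discrimination (CAD) screening
#' window. Defaults: dust PDR 0.25 (midpoint of the typical dust range
#' 0.2-0.3), non-dust PDR 0.045 (midpoint of 0.02-0.07), dust lidar
#' ratio 44 sr, CAD window `[-100, -90]` (confident aerosol only).
#'
#' @param delta_dust,delta_nondust Endmember PDRs, dimensionless;
#'   `delta_dust > delta_nondust >= 0` required.
#' @param lidar_ratio_dust Dust extinction-to-backscatter ratio, sr.
#' @param cad_window Closed interval of accepted CAD scores.
#' @return An object of class `retrieval_params`.
#' @export
retrieval_params <- function(delta_dust = 0.25, delta_nondust = 0.045,
                             lidar_ratio_dust = 44,
                             cad_window = c(-100, -90)) {
  if (delta_dust <= delta_nondust || delta_nondust < 0) {
    stop("require delta_dust > delta_nondust >= 0", call. = FALSE)
  }
  if (lidar_ratio_dust <= 0) stop("`lidar_ratio_dust` must be > 0",
                                  call. = FALSE)
  if (length(cad_window) != 2 || cad_window[1] > cad_window[2]) {
    stop("`cad_window` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  structure(list(delta_dust = delta_dust, delta_nondust = delta_nondust,
                 lidar_ratio_dust = lidar_ratio_dust,
                 cad_window = cad_window),
            class = "retrieval_params")
}

#' Screen profiles by cloud-aerosol discrimination score
#'
#' Levels whose CAD score falls outside the closed acceptance window are
#' flagged missing (backscatter and PDR set to `NA`); they stay missing
#' through all downstream means and are never treated as zeros. The
#' screening report (levels and whole profiles retained / removed) is
#' attached as attribute `"screening"`.
#'
#' @param granule A `lidar_granule`.
#' @param params A [retrieval_params()].
#' @return The granule with out-of-window levels masked. If everything is
#'   removed the (fully masked) granule is still returned, with a
#'   warning.
#' @export
screen_profiles <- function(granule, params = retrieval_params()) {
  stopifnot(inherits(granule, "lidar_granule"))
  w <- params$cad_window
  keep <- granule$cad >= w[1] & granule$cad <= w[2]
  keep[is.na(keep)] <- FALSE
  granule$beta_p[!keep] <- NA_real_
  granule$pdr[!keep] <- NA_real_
  report <- list(
    n_levels_total = length(keep),
    n_levels_kept = sum(keep),
    n_profiles_total = ncol(keep),
    n_profiles_kept = sum(colSums(keep) > 0)
  )
  if (report$n_levels_kept == 0) {
    warning("CAD screening removed every level", call. = FALSE)
  }
  attr(granule, "screening") <- report
  granule
}

#' Dust fraction of particulate backscatter from the depolarization ratio
#'
#' Two-component partition of the particulate backscatter coefficient:
#' for a mixture of a dust endmember (PDR `delta_dust`) and a non-dust
#' endmember (PDR `delta_nondust`), the dust share of total backscatter
#' implied by an observed composite PDR `delta` is
#' \deqn{f_d = \frac{(\delta - \delta_{nd})(1 + \delta_d)}
#'                  {(\delta_d - \delta_{nd})(1 + \delta)},}
#' clipped to `[0, 1]`. Observations at or above the dust endmember are
#' pure dust; at or below the non-dust endmember, dust-free. Intermediate
#' ("mixed dust") PDR values are partitioned continuously.
#'
#' @param pdr Observed particulate depolarization ratio(s), `>= 0`;
#'   `NA` propagates.
#' @param params A [retrieval_params()].
#' @return Dust backscatter fraction(s) in `[0, 1]`, same shape as `pdr`.
#' @examples
#' dust_fraction(c(0.045, 0.14, 0.25))
#' @export
dust_fraction <- function(pdr, params = retrieval_params()) {
  if (any(pdr < 0, na.rm = TRUE)) stop("`pdr` must be >= 0", call. = FALSE)
  dd <- params$delta_dust; dn <- params$delta_nondust
  f <- (pdr - dn) * (1 + dd) / ((dd - dn) * (1 + pdr))
  out <- pmin(pmax(f, 0), 1)
  if (is.matrix(pdr)) dim(out) <- dim(pdr)
  out
}

#' Dust extinction from dust backscatter
#'
#' Multiplies the dust backscatter coefficient by the characteristic dust
#' lidar ratio.
#'
#' @param beta_dust Dust backscatter, per km per sr (`>= 0`; `NA`
#'   propagates).
#' @param lidar_ratio_dust Dust lidar ratio, sr.
#' @return Dust extinction in the same spatial shape, per km. Multiply by
#'   1000 for the conventional Mm^-1.
#' @export
dust_extinction <- function(beta_dust, lidar_ratio_dust = 44) {
  if (any(beta_dust < 0, na.rm = TRUE)) {
    stop("`beta_dust` must be >= 0", call. = FALSE)
  }
  if (lidar_ratio_dust <= 0) stop("`lidar_ratio_dust` must be > 0",
                                  call. = FALSE)
  beta_dust * lidar_ratio_dust
}

#' Partition a screened granule into dust extinction profiles
#'
#' Applies [dust_fraction()] level-wise, multiplies by total backscatter
#' and the dust lidar ratio, and stores the per-level dust extinction
#' (per km) on the granule as `$dext`.
#'
#' @param granule A (screened) `lidar_granule`.
#' @param params A [retrieval_params()].
#' @return The granule with a `dext` matrix `[n_levels x n_profiles]`.
#' @export
partition_profiles <- function(granule, params = retrieval_params()) {
  stopifnot(inherits(granule, "lidar_granule"))
  f <- dust_fraction(granule$pdr, params)
  granule$dext <- dust_extinction(f * granule$beta_p,
                                  params$lidar_ratio_dust)
  granule
}

#' Column dust optical depth of one extinction profile
#'
#' Trapezoidal vertical integral of dust extinction from the surface to
#' the integration ceiling, skipping missing levels pairwise.
#'
#' @param dext Dust extinction per level, per km.
#' @param altitude Level altitudes, metres, strictly increasing.
#' @param z_top Integration ceiling, metres (default 7000: dust above
#'   7 km is treated as negligible).
#' @return Dimensionless optical depth; `NA` when fewer than two valid
#'   levels remain below the ceiling.
#' @examples
#' column_dod(rep(0.1, 5), seq(0, 2000, 500))  # 0.2
#' @export
column_dod <- function(dext, altitude, z_top = 7000) {
  if (length(altitude) != length(dext)) {
    stop("`dext` and `altitude` lengths differ", call. = FALSE)
  }
  if (any(diff(altitude) <= 0)) {
    stop("`altitude` must be strictly increasing", call. = FALSE)
  }
  sel <- altitude <= z_top & !is.na(dext)
  z <- altitude[sel] / 1000          # km
  a <- dext[sel]                     # km^-1
  if (length(z) < 2) return(NA_real_)
  sum(diff(z) * (a[-1] + a[-length(a)]) / 2)
}

# Internal constructor for the monthly gridded dust product.
# dext: [nlon, nlat, nalt, nmonth] in Mm^-1; dod recomputed as the
# rectangle-rule column integral so the dod/dext invariant holds by
# construction.
new_dust_grid <- function(grid, months, dext, n_samples) {
  nm <- length(months)
  dod <- array(NA_real_, c(grid$nlon, grid$nlat, nm))
  for (m in seq_len(nm)) {
    sl <- dext[, , , m, drop = FALSE]
    dim(sl) <- c(grid$nlon, grid$nlat, grid$nalt)
    part <- sweep(sl, 3, grid$dz, `*`) * 1e-6     # Mm^-1 * m -> dimensionless
    all_na <- apply(is.na(sl), c(1, 2), all)
    tot <- apply(part, c(1, 2), sum, na.rm = TRUE)
    tot[all_na] <- NA_real_
    dod[, , m] <- tot
  }
  structure(list(grid = grid, months = months, dext = dext,
                 dod = dod, n_samples = n_samples),
            class = "dust_grid")
}

#' @export
print.dust_grid <- function(x, ...) {
  cat(sprintf("<dust_grid> %dx%dx%d cells x %d month(s); mean DOD %.4g (%d sampled cells)\n",
              x$grid$nlon, x$grid$nlat, x$grid$nalt, length(x$months),
              mean(x$dod, na.rm = TRUE), sum(x$n_samples > 0)))
  invisible(x)
}

#' Aggregate partitioned profiles to the monthly dust grid
#'
#' Averages per-level dust extinction of all profiles falling in each
#' 2 x 2 degree cell and calendar month, after rebinning levels to the
#' grid's altitude bins (mean of levels within each bin). Cells with no
#' contributing profiles are missing, never zero. Profiles outside the
#' horizontal domain are dropped and counted.
#'
#' @param granule A `lidar_granule` that has been screened and
#'   partitioned (has `$dext`).
#' @param grid A [grid_def()].
#' @return A `dust_grid` with `dext` (Mm^-1), column `dod`, and
#'   `n_samples` per cell/month; the number of dropped profiles is
#'   attached as attribute `"n_dropped"`.
#' @export
grid_monthly <- function(granule, grid = grid_def()) {
  stopifnot(inherits(granule, "lidar_granule"))
  if (is.null(granule$dext)) {
    stop("granule has no `dext`; run partition_profiles() first",
         call. = FALSE)
  }
  months <- sort(unique(granule$month))
  nm <- length(months)
  loc <- locate_cells(grid, granule$lon, granule$lat)
  dropped <- is.na(loc$i)

  # Rebin levels -> altitude bins per profile (mean of in-bin levels).
  bin_of <- findInterval(granule$levels, grid$alt_edges,
                         rightmost.closed = TRUE)
  bin_of[bin_of < 1 | bin_of > grid$nalt] <- NA_integer_
  np <- length(granule$lat)
  dext_bin <- matrix(NA_real_, grid$nalt, np)    # km^-1
  for (b in seq_len(grid$nalt)) {
    rows <- which(bin_of == b)
    if (length(rows) == 0) next
    sub <- granule$dext[rows, , drop = FALSE]
    all_na <- colSums(!is.na(sub)) == 0
    m <- colMeans(sub, na.rm = TRUE)
    m[all_na] <- NA_real_
    dext_bin[b, ] <- m
  }

  acc <- array(0, c(grid$nlon, grid$nlat, grid$nalt, nm))
  cnt <- array(0L, c(grid$nlon, grid$nlat, grid$nalt, nm))
  nprof <- array(0L, c(grid$nlon, grid$nlat, nm))
  for (p in seq_len(np)) {
    if (dropped[p]) next
    m <- match(granule$month[p], months)
    i <- loc$i[p]; j <- loc$j[p]
    ok <- !is.na(dext_bin[, p])
    acc[i, j, ok, m] <- acc[i, j, ok, m] + dext_bin[ok, p]
    cnt[i, j, ok, m] <- cnt[i, j, ok, m] + 1L
    nprof[i, j, m] <- nprof[i, j, m] + 1L
  }
  dext <- ifelse(cnt > 0, acc / cnt, NA_real_) * 1e3   # km^-1 -> Mm^-1
  dim(dext) <- dim(acc)
  out <- new_dust_grid(grid, months, dext, nprof)
  attr(out, "n_dropped") <- sum(dropped)
  out
}
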