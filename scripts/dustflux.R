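#!/usr/bin/env Rscript
# Thin command-line wrapper over the dustflux package.
#
#   Rscript scripts/dustflux.R run   [--config cfg.yaml] [--seed N] [--out-dir DIR]
#   Rscript scripts/dustflux.R simulate [--seed N] [--out-dir DIR]
#
# `run` executes the full pipeline (simulate -> retrieve -> flux ->
# deposit -> statistics -> sensitivity); `simulate` only writes the
# synthetic granule and regional series. All numerics live in the
# package; this script only parses arguments.

suppressPackageStartupMessages(library(dustflux))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: dustflux.R <run|simulate> [options]")
cmd <- args[1]
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg_path <- opt("--config", NA)
cfg <- read_pipeline_config(if (is.na(cfg_path)) NULL else cfg_path)
seed <- opt("--seed", NA)
if (!is.na(seed)) cfg$seed <- as.integer(seed)
out_dir <- opt("--out-dir", "dustflux_out")

if (cmd == "run") {
  bundle <- run_pipeline(cfg, out_dir)
  cat(sprintf("pipeline done: deposition total %.4g Tg/yr, oracle error %.3g%%\n",
              bundle$deposition$totals$total_clipped_Tg_yr[1],
              bundle$oracle_deposition_error_pct))
} else if (cmd == "simulate") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- make_granule(granule_spec(n_profiles = cfg$granule$n_profiles,
                                 noise_sd_rel = cfg$granule$noise_sd_rel,
                                 cad_outlier_fraction =
                                   cfg$granule$cad_outlier_fraction,
                                 seed = cfg$seed))
  write_granule_csv(g, file.path(out_dir, "granule.csv"))
  s <- make_series(series_spec(n_years = cfg$series$n_years,
                               cross_corr = cfg$series$cross_corr,
                               seed = cfg$seed))
  write_series_csv(s, file.path(out_dir, "series.csv"))
  cat("wrote", file.path(out_dir, "granule.csv"), "and series.csv\n")
} else {
  stop("unknown command: ", cmd)
}
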