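Package: dustflux
Title: Satellite-Based Dust Transport and Deposition over Ocean Basins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies mineral dust transport and deposition over an
    oceanic domain from lidar-style aerosol profiles. Partitions
    particulate backscatter into dust and non-dust components with the
    two-component depolarization-ratio method, converts dust extinction
    to mass concentration via an assumed mass extinction efficiency,
    builds zonal and meridional dust mass-flux profiles from gridded
    winds, estimates per-cell deposition flux by the flux-divergence
    method, and derives dust loss frequency and lifetime. Includes
    gridded Mann-Kendall/linear-regression trend analysis, regional
    climatologies and anomaly correlations against ocean productivity
    and nitrate series, parameter sensitivity sweeps, and a synthetic
    data generator (lidar granules, advected plumes with analytically
    known deposition, correlated regional series) so the whole pipeline
    is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
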