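Package: phenoscope
Title: High-Resolution Land Surface Phenology from Dense Optical Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end land surface phenology (LSP) pipeline for dense,
    irregular 4-band surface-reflectance image time series over fixed site
    windows. Scenes are quality-masked, same-day acquisitions are mosaicked by
    averaging, and per-pixel two-band Enhanced Vegetation Index (EVI2) series
    are conditioned (de-spiking, snow screening, background flooring) and
    gap-filled with penalized cubic smoothing splines to daily resolution.
    Growth cycles are detected with amplitude and timing heuristics, and seven
    timing plus three greenness phenometrics with quality-assurance flags are
    encoded into a 24-layer per-site-per-year netCDF product. Includes a
    synthetic scene and trajectory generator with analytic ground truth for
    parameter-recovery testing, and raster/point comparison utilities
    (correlation, RMSE, bias with window averaging).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
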