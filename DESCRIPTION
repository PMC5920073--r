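Package: ld3d
Title: Quantification of Lipid Droplets in 3D Confocal Stacks of Oilseed
    Cotyledons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-calibrated quantification of lipid droplets (oil bodies)
    and cells in confocal z-stacks of oilseed cotyledon tissue. Segments
    Nile-Red-like fluorescence into individual droplets (global threshold,
    3D connected components, size filter, optional watershed splitting of
    touching droplets), segments or ingests cell label volumes, assigns
    droplets to cells, and computes per-droplet, per-cell and per-field
    morphometrics: droplet volumes and equivalent diameters, per-cell lipid
    volume fraction (VLD/VSC) and droplet counts (TNLD), field-level lipid
    fraction (VTLD/VTSF), and inter-cell spacing. Includes a ground-truthed
    synthetic field generator (cell tessellation, lognormal droplet sizes,
    PSF blur, shot and read noise) and line/group summary reports for
    high- versus low-oil comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
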