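Package: localrec
Title: Localized Reconstruction of Subunits from Cryo-EM Particle Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localized single-particle reconstruction of
    macromolecular subunits from electron cryomicroscopy images. Given
    refined whole-complex particle orientations, a point-group symmetry
    and a vector locating one subunit, the package derives sub-particle
    poses and positions by symmetry expansion, optionally subtracts the
    bulk-complex signal from the particle images, extracts sub-particles
    as independent single particles, reconstructs them by direct Fourier
    inversion, and assesses map quality by Fourier shell correlation and
    Guinier B-factor analysis. Reads and writes Relion-style STAR
    metadata, MRC2014 maps and stacks, and Chimera marker (CMM) files,
    and includes a synthetic phantom simulator so the whole workflow can
    be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
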