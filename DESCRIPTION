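Package: sonognp
Title: Quantitative Analysis of Ultrasound-Mediated Gold Nanoparticle Uptake
    and Intracellular Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free studies of ultrasound-assisted
    gold nanoparticle (GNP) delivery into cultured cells. Provides seeded
    synthetic-data generators for reflectance scenes, uptake time courses and
    voxelised cell masks; K-means plus intensity-threshold segmentation of
    reflectance images with equivalent-diameter cluster sizing and
    exposure-time regression; log-normal size-distribution fitting of
    nanoparticle-tracking-analysis histograms by damped least squares;
    conversion of ICP-AES gold mass concentrations to per-cell particle
    counts; constrained first-order absorption kinetics with a fixed
    asymptote and exact small-sample inference; and refractive-index-band
    morphometry of optical-diffraction-tomography volumes, including the
    membrane surface-area-to-volume ratio used as a sonoporation indicator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
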