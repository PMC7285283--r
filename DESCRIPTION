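Package: cwrq
Title: Quantification of Regenerating Cellulose Networks in Protoplast Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image analysis pipeline for quantifying nascent cellulose
    networks regenerating on the surface of plant protoplasts. Reads
    confocal z-stacks, computes maximum-intensity projections, extracts
    one-pixel-wide skeletons of the curvilinear fibril network with a
    Hessian ridge detector, and summarises each cell by four network
    features: total skeleton length, mean skeleton-pixel intensity,
    coefficient of variation and skewness of the intensity distribution
    (the latter two as bundling metrics). Also estimates fiber-diameter
    distributions from high-resolution electron-microscopy-like images
    via the distance transform, computes the osmotic-stability ratio
    from protoplast rupture counts, and provides the group-comparison
    tests used with these endpoints (exact/midrank Mann-Whitney,
    Tukey-Kramer with compact letter display, Student's t). A synthetic
    scene generator renders fluorescence and electron-microscopy-like
    images of fibril networks with known ground truth (total curve
    length, bundling factor, diameters) so every stage of the pipeline
    can be validated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
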