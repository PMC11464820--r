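Package: urbanmosaic
Title: Urban Land Cover from Tagged Geographic Features, Urbanization
    Indices, and Autologistic Occupancy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds high-resolution urban land-use/land-cover rasters from
    community-mapped geographic features carrying key-value tags (the
    OpenStreetMap vocabulary). Features are classified into a 27-class urban
    framework through an editable rule registry, linear features are buffered
    to polygons using per-lane widths, per-class layers are rasterized at 30 m
    and merged under a priority structure, and the result is backfilled from a
    coarse global land-cover product (with a 28th "developed unknown" class).
    Includes validation tools (completeness, stratified accuracy assessment
    with Cohen's kappa and per-class precision, paired-area regression), a
    wildlife-oriented urbanization index built from focal vegetation and
    building proportions and normalized distances to major roads and water,
    and maximum-likelihood autologistic multi-season occupancy models with
    AIC model competition for camera-trap detection histories. Synthetic-city
    and detection-history generators make the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    caret
Config/testthat/edition: 3
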