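Package: magtaxis
Title: Circular and Two-Choice Statistics for Magnetotaxis Plate Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of behavioral taxis assays in
    Caenorhabditis elegans and similar organisms. Implements the circular
    statistics used for horizontal-field orientation assays (mean vector
    summation, the second-order Rayleigh uniformity test on plate mean
    directions, von Mises kernel density estimation, and bootstrap
    confidence intervals for the mean resultant length), the preference
    index and two-sided Mann-Whitney U comparison used for two-target
    magnet and chemotaxis plate assays, plate-inclusion filters based on
    environmental metadata, CSV readers and writers for both assay
    layouts, and hierarchical synthetic-data generators that emulate
    plate-clustered worm headings and overdispersed two-target counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
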