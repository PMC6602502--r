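Package: orgmapr
Title: Physical Maps of Organellar Genomes from GenBank Annotations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts GenBank flat-file annotations of plastid,
    mitochondrial and other small replicons into publication-grade
    circular or linear physical maps. Includes a GenBank feature-table
    parser with origin-spanning locations, gene-class assignment with
    configurable colour schemes and an XML override format, gene-name
    tidy-up following organellar nomenclature conventions, sliding-window
    GC-content profiles, annotation-based and de novo inverted-repeat
    detection, degenerate restriction-site scanning, an expression-overlay
    (transcript) mode, deterministic SVG output with PDF/PostScript and
    raster conversions, a batch command-line driver, and a seeded
    synthetic-genome generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
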