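Package: opticorr
Title: DNA Sequence Search by Simulated Optical Image Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns DNA query sequences against a sequence database by coding
    nucleotides as grayscale pixel intensities and searching for the query
    image inside fixed-size database "scene" images with a digitally
    simulated Vander-Lugt optical correlator.  Correlation is computed in the
    frequency domain with a phase-only filter; presence and position of a
    query are decided from the correlation peak against a calibrated
    intensity threshold.  Includes a synthetic benchmark generator
    (random databases, randomly extracted queries, substitution-mutated
    query sets), sensitivity/specificity/exactitude/error scoring,
    threshold calibration, peak-localization reports, and command-line
    entry points for simulation, search and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    jsonlite
Config/testthat/edition: 3
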