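Package: tilescreen
Title: Saturating CRISPR Tiling-Screen Simulation and Functional-Domain Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design saturating sgRNA tiling libraries over a coding sequence
    (every SpCas9 NGG protospacer-adjacent motif on both strands, cut sites
    mapped to residue coordinates), model diploid Cas9 repair outcomes
    (frameshift versus in-frame alleles) and the resulting loss-of-function
    cell fractions under selection, forward-simulate pooled dropout screens
    with known implanted functional domains, score per-guide depletion
    against non-targeting controls, smooth the depletion signal along the
    protein with a Gaussian kernel, and call high-ranking functional regions
    against a permutation null with false-discovery-rate control. Includes
    readers and writers for the library, count-matrix and region formats, a
    configurable end-to-end pipeline, and recovery metrics against simulated
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
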