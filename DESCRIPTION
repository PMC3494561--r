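Package: evoprimer
Title: Specific-Product PCR Primer Design by Genetic and Memetic Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs specific-product PCR primer pairs on user-supplied DNA
    templates by genetic-algorithm (GA) and memetic-algorithm (MA, GA plus
    local search) optimization of a multi-constraint penalty covering primer
    length, length difference, GC content, nearest-neighbor melting
    temperature with salt correction, Tm difference, product size,
    cross-/self-dimers, hairpins, GC clamp and template specificity.
    Candidate pairs are ranked by penalty and Tm difference and written to a
    plain-text report with secondary-structure markers.  Includes local
    in-silico PCR amplicon prediction (amplicons re-usable as redesign
    templates), virtual gel electrophoresis with a molecular-size ladder,
    a high-throughput batch mode over multi-FASTA input, and a seeded
    fixture generator producing templates with planted feasible pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
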