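Package: dualguide
Title: Dual sgRNA CRISPR/Cas9 Editing Analysis for Plant Functional Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of a dual-sgRNA CRISPR/Cas9
    mutagenesis workflow in Arabidopsis thaliana: protospacer localisation and
    blunt cut-site arithmetic, paired-guide deletion and reading-frame
    prediction, decomposition of mixed Sanger-trace peak signals into indel
    spectra by non-negative least squares with editing-efficiency and
    chimerism statistics, classification of repair junctions as cNHEJ, MMEJ or
    synthesis-dependent MMEJ (loop-out and snap-back, with primer-repeat and
    microhomology arithmetic), chi-squared transgene segregation testing,
    in-silico PCR genotyping, and a fully seeded synthetic-data generator that
    emulates chimeric T1 plants, four-channel trace signals and Mendelian T2
    populations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
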