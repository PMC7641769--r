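Package: g4pombe
Title: G-Quadruplex Replication Obstacles in Fission Yeast: Motif
    Scanning, Peak Enrichment and Single-Molecule Damage Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying how stabilized G-quadruplex
    (G4) structures impede DNA replication in Schizosaccharomyces pombe.
    Provides a G4 motif scanner ((G>=3 N1-25)3 G>=3, with a two-tetrad
    mode and polymerase stall-site annotation), ChIP-seq peak/feature
    enrichment accounting (coverage, overlap counts, GC content, fold
    changes, top-N selection and the pseudo-replicate Np/Nt reliability
    ratio), single-molecule DNA-damage quantification from two-channel
    images of stretched DNA (backbone tracing, spot detection, dots per
    micrometre and per Mbp), closed-form assay quantifications (fiber
    tract statistics, doubling time, helicase unwinding fraction, molar
    ellipticity, qPCR-stop relative amplification), and a synthetic-data
    module that generates all inputs with ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
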