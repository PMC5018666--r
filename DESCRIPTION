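Package: wrkyscan
Title: Genome-Wide Identification and Characterization of WRKY Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for genome-wide identification and
    characterization of WRKY transcription-factor gene families.
    Detects WRKY domains (WRKYGQK heptapeptide variants plus spaced
    C2H2/C2HC zinc fingers) by pattern scanning, classifies proteins into
    groups I, IIa-IIe and III, computes protein physicochemical properties
    and exon-intron structure (including R-/V-type intron placement),
    orders and renames genes along chromosomes, calls 200-kb gene clusters,
    classifies tandem versus segmental duplications, infers reciprocal-best-hit
    orthologs, estimates Ka/Ks by the Nei-Gojobori counting method, builds
    neighbor-joining phylogenies with bootstrap support, and profiles RPKM
    expression across tissues.  Ships a synthetic-genome generator with a
    ground-truth manifest so every stage is testable without downloads, and a
    transcribed willow (Salix suchowensis) family characterization table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
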