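Package: haploscreen
Title: Pooled Suppressor-Screen Simulation and Candidate-Gene Mapping
    for Haploid Chemical Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for forward-genetic suppressor screens in chemically
    mutagenized haploid cells analysed by pooled exome-style sequencing.
    Simulates toy genomes, ENU-mutagenized clones with planted causal
    resistance alleles, and pooled per-site read counts with sequencing
    error and strand structure; calls low-frequency variants with a
    binomial likelihood-ratio model against a globally estimated error
    rate plus an exact strand-bias filter; subtracts an unselected
    control pool; annotates coding consequences against gene models;
    ranks candidate genes by recurrent protein-altering hits per
    kilobase of coding sequence; and maps candidate substitutions onto
    protein-ligand complexes to classify binding-interface proximity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    bio3d,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
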