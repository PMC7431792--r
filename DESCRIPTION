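Package: fragrec
Title: Competitive Fragment Recruitment for Viral Metagenomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates phage genomes (consensus open reading frame calling on
    circular genomes and a thresholded-energy screen for rho-independent
    terminators), searches metagenomic reads against phage proteomes by
    six-frame translated local alignment with Karlin-Altschul E-value
    statistics, recruits reads to a focal phage by competitive best-hit
    assignment against a composite phage protein database, and summarises
    recruitment as per-ORF or per-genome-length normalized abundances across
    metagenomes. A synthetic-community generator with a ground-truth table
    makes the whole pipeline verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
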