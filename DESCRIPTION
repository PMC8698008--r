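Package: haplodeficit
Title: Reverse Genetic Screening for Recessive Lethal Haplotypes in
    Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Mara", "Keller", email = "mara.keller@posteo.net",
           role = c("aut", "cre"))
Description: A missing-homozygosity screen for deleterious recessive
    haplotypes in SNP-genotyped, pedigreed livestock populations.
    Enumerates haplotypes in sliding marker windows over phased
    genotypes, tests each for a deficit of homozygous animals with an
    exact Hardy-Weinberg test, controls the false discovery rate with
    the Benjamini-Yekutieli procedure, merges significant windows into
    candidate regions, and links regions to protein-changing candidate
    variants in a sequenced carrier panel via linkage disequilibrium
    (r^2) between diplotype state and variant genotype dosage. Includes
    a gene-drop pedigree simulator with embedded recessive-lethal
    haplotypes so every stage is testable without proprietary breed
    data, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
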