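Package: amplimosaic
Title: Mosaic G0 CRISPR Amplicon Genotyping with Microhomology Deletion
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping toolkit for mosaic G0-generation CRISPR/Cas9 embryos
    carrying mixtures of differently repaired alleles across homeologous loci.
    Locates gRNA target sites and Cas9 cut positions, applies the seed-sequence
    activity rule, enumerates microhomology-mediated end-joining (MMEJ)
    deletion products around a double-strand break, assigns amplicon reads to
    homeologous alleles, calls and right-normalizes DNA lesions inside a
    PAM-anchored variant window, annotates protein consequences in HGVS p.
    notation (including splice-acceptor exon-skip and splice-donor
    intron-retention assumptions), grades each allele on a six-level genotype
    score, aggregates per-embryo mosaic allele spectra, and tests the
    association between wild-type allele presence and phenotype with an exact
    hypergeometric test. A seeded simulator generates synthetic mosaic-embryo
    cohorts with a per-read ground-truth manifest for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
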