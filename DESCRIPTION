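Package: genomepair
Title: Gene-Level Comparison of Paired Annotated Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two annotated assemblies of the same
    species that share gene and transcript identifiers, as produced by an
    annotation lift-over. Classifies every transcript pair into one of ten
    coding-effect categories (identical, synonymous, nonsynonymous, in-frame
    insertion/deletion, start-codon loss, 5'/3' truncation, frameshift,
    stop-codon gain), rolls verdicts up to genes via a representative
    isoform, triages candidate deleterious genes with a homozygous
    non-SNP variant rescue, validates tandem ribosomal DNA units by the
    18S-5.8S-28S order condition, validates nuclear mitochondrial
    insertions (NUMTs) by spanning long-read alignments, accounts for
    donor-sequence provenance via lowercase soft-masking, and compares
    paralog cluster copy numbers between the assemblies. Includes a
    deterministic synthetic genome-pair simulator that plants every effect
    category with known ground truth so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
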