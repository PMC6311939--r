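Package: mirseek
Title: Small RNA Profiling, Novel miRNA Discovery and Degradome Target Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for plant small-RNA sequencing studies:
    adapter trimming and tag collapsing, hierarchical classification of tags
    against reference sets, conserved miRNA family assignment with reads-per-
    ten-million (RPTM) normalization, novel miRNA discovery from genome-mapped
    tags requiring a sequenced miRNA-star and a predicted fold-back precursor,
    and miRNA cleavage-target identification from degradome (PARE) 5'-end
    evidence using a G:U-wobble-aware mismatch score and a valid-reads-at-
    cleavage-site statistic. Includes a seeded synthetic-study generator
    (genome with planted hairpins, multi-genotype libraries, transcriptome
    with planted cleavage sites) for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
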