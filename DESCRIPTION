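Package: mdmbench
Title: Benchmarking Taxonomic Profilers in Undercharacterized Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs realistic synthetic metagenomic communities with a
    controlled fraction of uncharacterized ("dark matter") species and
    evaluates taxonomic-profiler outputs against the known truth. Includes
    NCBI-style taxonomy parsing and name harmonization, genome-catalog
    curation rules, log-normal community design with genome-size matching
    and read-simulator (CAMISIM) configuration emission, profile
    post-processing (abundance thresholding, unknown-mass handling, rank
    aggregation, restriction to NCBI-available taxa), rank-wise accuracy
    and community-structure metrics, and MinHash-based assessment of
    metagenome-assembled-genome recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
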