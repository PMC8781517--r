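Package: stingnet
Title: Pathway-Level Integration of Venom-Gland Transcriptomes and
    High-Content Screening Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-pharmacology toolkit for fish venom research. Filters
    sequence-similarity annotations of venom-gland transcriptomes (identity,
    coverage, bit-score and expression thresholds; best hit per reference
    accession), summarises toxin-family relative expression and cross-species
    family overlap, builds control-normalised cytological profiles from
    high-content screening (HCS) well data, clusters them by complete linkage
    under Spearman rank-correlation distance, and integrates both data types
    at the signalling-pathway level into a tripartite entity-pathway-system
    network from which symptom-specific subnetworks (for example pain) are
    extracted. Ships a synthetic-fixture generator with planted ground truth
    so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
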