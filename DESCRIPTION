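Package: pgsrank
Title: Reciprocal-Rank Aggregation of Polygenic Score Variants into a Queryable Rank Database
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses PGS Catalog harmonized scoring files, merges the scores
    mapped to a trait into a single dataset, ranks variants within each score
    by the absolute value of their effect weights, and aggregates ranks across
    scores with the Dowdall (reciprocal-rank) positional method to a mean
    reciprocal rank (MRR) per variant. Variant scores can be rolled up to
    genes through a precomputed annotation table, and the resulting trait,
    score, variant-rank, gene-rank and summary-statistic tables are
    materialized into a single SQLite database with deterministic top-N
    queries. Includes a seeded synthetic scoring-file generator with an
    independent brute-force oracle, and a minimal PGS Catalog REST client for
    trait-based score discovery and download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
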