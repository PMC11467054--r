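# pgsrank

Rank-aggregate the variants of published polygenic scores into a queryable
trait-specific variant/gene rank database.

## The problem

A polygenic score (PGS) is a weighted sum of trait-associated allele counts;
the PGS Catalog distributes each published score as a harmonized scoring
file listing variants (rsIDs and/or GRCh38 coordinates), effect alleles and
signed per-allele effect weights. For a well-studied trait such as
Alzheimer's disease, dozens of scores exist, each built from different GWAS
data with different methods — so "which variants matter most for this
trait?" has no single-file answer. `pgsrank` answers it by treating each
score as a *ballot* and aggregating across scores with the Dowdall method,
a Borda-family positional voting rule:

* within each score, variants are ranked by descending absolute effect
  weight **|w|**, and the variant at rank *i* receives the reciprocal rank
  **RR = 1/i** (1, 1/2, 1/3, ...; exactly tied |w| blocks share the mean of
  1/position over the block);
* across a trait's *N* scores, each variant's mean reciprocal rank is

  **MRR(v) = (1/N) · Σ<sub>s=1..N</sub> RR<sub>s</sub>(v)**,

  where RR<sub>s</sub>(v) = 0 when the variant is absent from score *s* or
  its weight is missing (`NA`). A variant with no usable weight anywhere is
  assigned MRR 0 rather than dropped.

MRR ∈ [0, 1] and equals 1 only for a variant that is the unique top of
every score — the statistic rewards variants that carry a large effect
weight *consistently* across scores. Variant MRRs roll up to genes through
a precomputed variant→gene annotation table (ANNOVAR-multianno-style TSV):
a gene's score is the maximum MRR among its annotated variants. Everything
lands in a single SQLite file with five constrained tables (`traits`,
`scores`, `variant_ranks`, `gene_ranks`, `summary`) and deterministic
top-N queries.

## Worked example

Fully offline, using the seeded synthetic corpus generator (five scoring
files, 200 variants each, partially overlapping, 10% missing weights, one
variant planted as every file's strongest):

```r
library(pgsrank)

spec <- fixture_spec(n_files = 5, planted_top = "rs999", seed = 42,
                     trait = "demo trait")
corpus <- generate_corpus(spec, tempdir())

res <- rank_trait("demo trait", corpus$paths)
head(res$ranks, 3)
#> # A tibble: 3 × 5
#>   trait      variant_key   mrr n_present n_pgs
#>   <chr>      <chr>       <dbl>     <int> <int>
#> 1 demo trait rs999       1             5     5
#> 2 demo trait rs904787743 0.116         5     5
#> 3 demo trait rs907413905 0.110         5     5

res$summary
#> # A tibble: 1 × 9
#>   trait      n_files  w_min w_max   mean  median    sd n_rows single_obs
#>   <chr>        <int>  <dbl> <dbl>  <dbl>   <dbl> <dbl>  <int> <lgl>
#> 1 demo trait       5 -0.967  3.98 0.0235 0.00126 0.321    873 FALSE

db <- build_rank_db(res$dataset, res$ranks, summaries = res$summary,
                    path = file.path(tempdir(), "rank.sqlite"))
query_top_variants(db, "demo", 2)   # case-insensitive substring match
#> # A tibble: 2 × 5
#>   trait      variant_key   mrr n_present n_pgs
#>   <chr>      <chr>       <dbl>     <int> <int>
#> 1 demo trait rs999       1             5     5
#> 2 demo trait rs904787743 0.116         5     5
```

The planted variant recovers MRR 1 and rank 1; `mrr` is each variant's mean
reciprocal rank over all five scores, `n_present` the number of scores in
which it carries a usable weight. With an annotation table,
`rank_trait(..., annotation = "multianno.txt")` also returns gene scores,
queryable via `query_top_genes()` (each gene appears exactly once).

Real scoring files are parsed the same way — `read_scoring_file()` accepts
plain or gzipped PGS Catalog harmonized files — and for users with network
access `pgs_score_ids("Alzheimer's disease")` /
`pgs_fetch_scoring_files(ids, outdir)` discover and download a trait's
harmonized GRCh38 files from the PGS Catalog REST API, filtered to a
release-date cutoff (default 2023-08-04).

A thin command-line front end is installed at
`system.file("scripts/pgsrank", package = "pgsrank")` with subcommands
`build-db`, `top`, `summarize` and `gen-fixtures`.

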