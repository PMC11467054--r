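---
title: "Reciprocal-rank aggregation of polygenic score variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal-rank aggregation of polygenic score variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsrank)
```

## The model

Each polygenic score (PGS) assigns a signed per-allele effect weight $w$ to
every variant it uses. `pgsrank` treats each score mapped to a trait as one
*ballot* in a positional election over variants. Within a score, variants
with a non-missing weight are ordered by descending $|w|$ and the variant
at position $i$ receives the reciprocal rank $RR = 1/i$ — the Dowdall
variant of the Borda count. Across a trait's $N$ scores the variant's mean
reciprocal rank is

$$\mathrm{MRR}(v) \;=\; \frac{1}{N}\sum_{s=1}^{N} RR_s(v),$$

with $RR_s(v) = 0$ whenever $v$ is absent from score $s$ or its weight is
missing. Consequences worth stating explicitly:

* $\mathrm{MRR} \in [0,1]$; it equals 1 **iff** the variant is the unique
  top-ranked variant of every score, and 0 **iff** it has no usable weight
  anywhere (such variants are emitted with MRR 0, not dropped — presence
  without a weight is still information).
* The reciprocal decays fast, so MRR is dominated by top positions: it is
  a *consistency-of-top-rank* statistic, not an average effect size.
* Because ranking uses $|w|$ only, MRR is invariant to multiplying any
  score's weights by a positive constant and to flipping any weight's
  sign. Scores built on different scales therefore need no
  standardization before aggregation (and none is applied).

### Assumptions and what the statistic does *not* model

Each ballot is weighted equally regardless of its GWAS sample size, method
or ancestry, and sample overlap between the source GWAS of different
scores is ignored — two near-duplicate scores count as two independent
ballots. Effect weights are compared only within a score, never across
scores. These are deliberate properties of a rank-based method, and its
main limitations.

## Key choices where the method is genuinely open

**Denominator of the mean.** MRR divides by the trait's total score count
$N$, so a variant absent from most scores is penalized even if top-ranked
where present. This matches the consistency-reward reading and the
Borda-family convention of summing over all ballots. The alternative —
dividing by the number of scores where the variant has a usable weight —
is available as `aggregate_mrr(ds, denominator = "files_present")` for
comparison; it measures "how good where present" instead.

**Per-file ranking.** Ranks are computed within each scoring file, then
averaged — not on a pooled table. Pooling would compare weights across
scores, which the scale-invariance requirement forbids.

**Ties.** Exactly equal $|w|$ within a file (weights originate as decimal
text, so equal text means equal parsed doubles; no epsilon is used) form a
block spanning positions $s..s{+}k{-}1$ that shares
$\frac{1}{k}\sum_{j=s}^{s+k-1} 1/j$. This keeps the per-file total
$\sum RR = H(n)$, the $n$-th harmonic number, ties or not — a conservation
law the tests assert to $10^{-12}$ — and makes the ranking independent of
input row order. Untied variants receive exactly $1/\mathrm{rank}$
(computed directly, not via cumulative-sum differences, so the worked
values 1, 1/2, 1/3 are bit-exact).

**One candidate, one position per ballot.** If a file lists the same
variant key twice, only the occurrence with the largest $|w|$ is kept
(missing loses to any value; exact ties keep the first occurrence), with a
warning. Across files no deduplication occurs — each file is a separate
ballot.

**Cross-dialect identity.** Keys are canonical: harmonized rsID, then raw
rsID, then harmonized `chr:pos`, then raw `chr:pos`; rsIDs lower-cased
with the `rs` prefix enforced, chromosomes stripped of `chr` and
upper-cased. An rsID-keyed and a coordinate-keyed occurrence of the same
physical variant are **not** unified — that would need an external
rsID↔position map — so a variant split across key forms is counted as two
candidates. This is the method's main known data-hygiene limitation and is
why harmonized files, which carry both forms, are the preferred input.

**Gene rollup.** The variant→gene map is consumed as a precomputed
annotation table; a gene's score is the **maximum** MRR among its mapped
variants (a gene is prioritized by its best variant; a sum would favour
long genes), with multi-gene variants contributing to every mapped gene
and unannotated variants skipped with a reported count. Gene symbols are
unique per trait by construction, so top-N gene queries never show
duplicates.

**Ordering.** All rank tables and queries order by score descending, then
key/gene ascending, so "top N" is reproducible under ties.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `denominator` | `aggregate_mrr()` | `"all_files"` | consistency reward (above) |
| missing tokens | reader | `NA`, `""`, `.` in; `NA` out | tolerant reader, strict writer |
| `release_cutoff` | `pgs_score_ids()` | `2023-08-04` | catalog release the shipped database derives from; the live API serves current state, so historical reproduction is best-effort |
| trait matching | queries | case-insensitive, substring fallback | "Alzheimer" should resolve to "Alzheimer's disease"; ambiguity is an error, never a guess |

Coordinates are 1-based GRCh38 throughout and never lifted over; no
allele-strand flipping or effect-allele harmonization is attempted.

## The synthetic corpus generator

`fixture_spec()`/`generate_corpus()` emulate the structural features of a
trait's scoring-file set that the method actually touches: several files
with a partially shared variant pool (`overlap`, default 0.5), signed
weights drawn as $\mathcal{N}(0, \sigma)$ with $\sigma = 0.04$ — the order
of real per-trait weight spreads — times a per-file log-uniform scale in
$[0.1, 10]$, so magnitudes span several orders and scientific-notation
parsing is exercised; 10% missing weights; 30% coordinate-keyed variants;
and label-dialect noise (upper-case `RS`, `chr`-prefixed chromosomes) to
exercise key normalization. A `planted_top` variant can be forced to carry
the strictly largest $|w|$ in every file, giving a known MRR of exactly 1
end-to-end. Per-file random streams are derived independently from the
corpus seed, so adding a file never perturbs earlier files, and the same
spec yields byte-identical output.

The generator does **not** simulate linkage disequilibrium, allele
frequencies, genotypes, or any correlation between a variant's weights
across files beyond shared membership. Passing tests therefore demonstrate
the correctness of parsing, merging, ranking, aggregation and querying —
not that MRR is a well-calibrated prioritizer on real GWAS-derived
weights.

An independent oracle (`oracle_mrr()`) recomputes every MRR from the
generator's ground-truth manifest by re-sorting and re-averaging from
scratch, sharing no code with the pipeline; the suite requires agreement
within $10^{-12}$ on 200 random corpora. Validation problem sizes — up to
6 files × 50 variants for the oracle sweep, a 23/5/5-file three-trait
study at 200 variants per file for the end-to-end run — were chosen as the
smallest sizes at which every code path (ties, missingness, overlap,
planted tops, both key dialects) is routinely exercised.

## Degenerate inputs, by policy

* A scoring file with an empty data section, a missing `effect_weight`
  column, an unparseable weight, or a malformed accession is rejected
  whole; rows lacking any locatable identifier are dropped with a count.
* A file whose weights are all missing contributes no ranks (warning); a
  trait with no usable weight at all has no summary (error).
* A single weight yields `sd = 0` with a `single_obs` flag rather than
  `NA`, keeping the summary table schema closed.
* Database builds are atomic (temp file, rename on success) and enforce
  primary-key, foreign-key and range constraints; a violation aborts the
  build and removes the temp file.

## Weight summaries

`trait_summary()` reports min, max, mean, median and sample ($n-1$)
standard deviation over *occurrence rows*: every non-missing weight counts
once per file it appears in, after within-file deduplication — the natural
statistics of the row-bound merged dataset. Summarizing unique variants
instead would require choosing one weight per variant across files, which
has no canonical answer.
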