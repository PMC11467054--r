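#' pgsrank: reciprocal-rank aggregation of polygenic score variants
#'
#' Builds a queryable variant/gene rank database from PGS Catalog scoring
#' files. Each score is treated as a ballot: its variants are ranked by
#' descending absolute effect weight and assigned the reciprocal of their
#' rank (Dowdall positional scoring), and a variant's ranks are averaged
#' across a trait's scores into a mean reciprocal rank (MRR). High MRR
#' marks variants that carry a large effect weight consistently across
#' scores. Variant scores roll up to genes through a precomputed
#' variant-to-gene annotation table, and all tables land in one SQLite
#' file with deterministic top-N queries.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

#' Run the scoring-files-to-rank-tables pipeline for one trait
#'
#' Convenience wrapper chaining [read_scoring_file()],
#' [merge_trait_files()], [aggregate_mrr()], [trait_summary()] and
#' (when an annotation table is given) [gene_scores()].
#'
#' @param trait Trait name.
#' @param score_paths Paths to the trait's scoring files.
#' @param annotation Optional annotation tibble
#'   ([load_annotation_table()] output) or a path to an annotation table.
#' @param denominator Passed to [aggregate_mrr()].
#' @return List with elements `dataset` (`pgs_trait_dataset`), `ranks`,
#'   `summary`, and `genes` (`NULL` without annotation).
#' @export
rank_trait <- function(trait, score_paths, annotation = NULL,
                       denominator = "all_files") {
  files <- lapply(score_paths, read_scoring_file)
  ds <- merge_trait_files(trait, files)
  ranks <- aggregate_mrr(ds, denominator = denominator)
  genes <- NULL
  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      annotation <- load_annotation_table(annotation)
    }
    genes <- gene_scores(ranks, annotation)
  }
  list(
    dataset = ds,
    ranks = ranks,
    summary = trait_summary(ds),
    genes = genes
  )
}
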