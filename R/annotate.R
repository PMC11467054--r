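#' Roll variant MRR scores up to genes
#'
#' Maps each ranked variant to its annotated gene(s) and scores every gene
#' by the *maximum* MRR among its mapped variants: a gene is prioritized by
#' its best variant, which keeps the score in \[0, 1\] and avoids favouring
#' long genes the way a sum would. A variant annotated to several genes
#' contributes to each of them; variants absent from the annotation table
#' are skipped (the count is reported). Gene symbols are unique in the
#' output by construction, so a "show each gene once" query needs no
#' post-hoc deduplication.
#'
#' @param ranks Tibble of variant rank records from [aggregate_mrr()]
#'   (a single trait).
#' @param ann Annotation tibble from [load_annotation_table()] (columns
#'   `variant_key`, `gene`, optionally `category`).
#' @return Tibble of gene rank records -- columns `trait`, `gene`, `score`,
#'   `n_variants`, `best_variant` -- sorted by `score` descending then
#'   `gene` ascending. `best_variant` is the variant attaining the score
#'   (lexicographically smallest key on an exact tie).
#' @export
gene_scores <- function(ranks, ann) {
  stopifnot(length(unique(ranks$trait)) <= 1L)
  empty <- tibble::tibble(
    trait = character(), gene = character(), score = double(),
    n_variants = integer(), best_variant = character()
  )
  if (is.null(ann) || nrow(ann) == 0L) {
    warning("empty annotation mapping; no gene scores computed", call. = FALSE)
    return(empty)
  }
  if (nrow(ranks) == 0L) return(empty)

  hits <- dplyr::inner_join(
    ranks[, c("trait", "variant_key", "mrr")],
    dplyr::distinct(ann[, c("variant_key", "gene")]),
    by = "variant_key",
    relationship = "many-to-many"
  )
  n_skipped <- sum(!(unique(ranks$variant_key) %in% ann$variant_key))
  if (n_skipped > 0L) {
    message(n_skipped, " ranked variant(s) without gene annotation skipped")
  }
  if (nrow(hits) == 0L) return(empty)

  hits <- hits[order(-hits$mrr, hits$variant_key), ]
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$trait, .data$gene),
    score = .data$mrr[1],
    n_variants = dplyr::n_distinct(.data$variant_key),
    best_variant = .data$variant_key[1],
    .groups = "drop"
  )
  out <- out[order(-out$score, out$gene), ]
  tibble::as_tibble(out)
}

#' Export a gene rank table as tab-separated text
#'
#' @param genes Tibble from [gene_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}
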