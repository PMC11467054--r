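#' Dowdall reciprocal ranks within one polygenic score
#'
#' Ranks the variants of a single scoring file by descending absolute effect
#' weight and assigns each the reciprocal of its rank: the top variant gets
#' 1, the second 1/2, the third 1/3, and so on (the Dowdall positional rule,
#' with each score acting as one ballot). Rows with a missing weight are
#' excluded from the ranking. Exactly tied |weight| blocks all receive the
#' mean of `1/position` over the block's positions, which keeps the per-file
#' total \eqn{\sum rr} equal to the harmonic number \eqn{H(n)} whether or
#' not ties occur.
#'
#' @param file_rows Tibble of one score's merged rows: columns `pgs_id`
#'   (single value), `variant_key`, `effect_weight`.
#' @return Tibble with columns `pgs_id`, `variant_key`, `rank` (smallest
#'   position of the variant's tie block), `rr`; ordered by rank then
#'   `variant_key`. Empty (with a warning) when every weight is missing.
#' @examples
#' rows <- tibble::tibble(
#'   pgs_id = "PGS000001",
#'   variant_key = c("rsA", "rsB", "rsC"),
#'   effect_weight = c(0.5, -0.9, 0.1)
#' )
#' rank_within_pgs(rows)  # rsB rr 1, rsA rr 1/2, rsC rr 1/3
#' @export
rank_within_pgs <- function(file_rows) {
  stopifnot(length(unique(file_rows$pgs_id)) <= 1L)
  x <- file_rows[!is.na(file_rows$effect_weight), ]
  if (nrow(x) == 0L) {
    warning(
      "all effect weights missing for ",
      if (nrow(file_rows)) file_rows$pgs_id[1] else "score",
      "; it contributes no ranks",
      call. = FALSE
    )
    return(tibble::tibble(
      pgs_id = character(), variant_key = character(),
      rank = integer(), rr = double()
    ))
  }
  aw <- abs(x$effect_weight)
  r_min <- rank(-aw, ties.method = "min")
  block_size <- stats::ave(r_min, r_min, FUN = length)
  # untied variants get exactly 1/rank; a tie block spanning positions
  # s..s+k-1 shares mean(1/s, ..., 1/(s+k-1))
  rr <- 1 / r_min
  for (s in unique(r_min[block_size > 1L])) {
    sz <- block_size[r_min == s][1]
    rr[r_min == s] <- mean(1 / (s:(s + sz - 1L)))
  }
  out <- tibble::tibble(
    pgs_id = x$pgs_id,
    variant_key = x$variant_key,
    rank = as.integer(r_min),
    rr = rr
  )
  out[order(out$rank, out$variant_key), ]
}

#' Aggregate reciprocal ranks across a trait's scores into MRR
#'
#' For every distinct variant key in a trait dataset, averages the variant's
#' per-score reciprocal ranks into a mean reciprocal rank (MRR). A score in
#' which the variant is absent, or present only with a missing weight,
#' contributes 0 to the sum; a variant with no usable weight anywhere is
#' assigned MRR 0 rather than dropped. With the default denominator the mean
#' is taken over all of the trait's scores (`n_pgs`), which rewards variants
#' that carry a large weight *consistently* across scores; the
#' `"files_present"` alternative divides by the number of scores where the
#' variant has a usable weight, for comparison.
#'
#' @param ds A `pgs_trait_dataset` from [merge_trait_files()].
#' @param denominator `"all_files"` (default) or `"files_present"`.
#' @return Tibble of variant rank records -- columns `trait`, `variant_key`,
#'   `mrr`, `n_present`, `n_pgs` -- sorted by `mrr` descending then
#'   `variant_key` ascending.
#' @export
aggregate_mrr <- function(ds, denominator = c("all_files", "files_present")) {
  stopifnot(inherits(ds, "pgs_trait_dataset"), ds$n_pgs >= 1L)
  denominator <- match.arg(denominator)

  merged <- ds$merged_rows
  ranked <- dplyr::bind_rows(lapply(
    split(merged, merged$pgs_id),
    rank_within_pgs
  ))

  keys <- sort(unique(merged$variant_key))
  rr_sum <- stats::setNames(numeric(length(keys)), keys)
  n_present <- stats::setNames(integer(length(keys)), keys)
  if (nrow(ranked) > 0L) {
    agg <- dplyr::summarise(
      dplyr::group_by(ranked, .data$variant_key),
      rr_sum = sum(.data$rr), n_present = dplyr::n(),
      .groups = "drop"
    )
    rr_sum[agg$variant_key] <- agg$rr_sum
    n_present[agg$variant_key] <- agg$n_present
  }

  denom <- if (denominator == "all_files") ds$n_pgs else pmax(n_present, 1L)
  out <- tibble::tibble(
    trait = ds$trait,
    variant_key = keys,
    mrr = unname(rr_sum / denom),
    n_present = unname(n_present),
    n_pgs = ds$n_pgs
  )
  out[order(-out$mrr, out$variant_key), ]
}

#' Export a variant rank table as tab-separated text
#'
#' @param ranks Tibble from [aggregate_mrr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(ranks, path) {
  readr::write_tsv(ranks, path, progress = FALSE)
  invisible(path)
}
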