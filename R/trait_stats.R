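#' Per-trait summary statistics of effect weights
#'
#' Computes the weight range, mean, median and standard deviation of a
#' trait's merged effect weights -- the per-phenotype "SNP info" summary of
#' the rank database. Statistics are taken over *occurrence rows*: every
#' non-missing weight in the merged dataset counts once per file it occurs
#' in (within-file duplicates have already been resolved upstream by
#' [merge_trait_files()]). Missing weights are excluded from every
#' statistic. The standard deviation uses the sample (n-1) denominator; a
#' single observation yields `sd = 0` with `single_obs = TRUE` rather than
#' `NA`, for schema simplicity.
#'
#' @param ds A `pgs_trait_dataset` from [merge_trait_files()].
#' @return One-row tibble: `trait`, `n_files`, `w_min`, `w_max`, `mean`,
#'   `median`, `sd`, `n_rows`, `single_obs`.
#' @export
trait_summary <- function(ds) {
  stopifnot(inherits(ds, "pgs_trait_dataset"))
  w <- ds$merged_rows$effect_weight
  w <- w[!is.na(w)]
  if (length(w) == 0L) {
    stop(
      "trait ", ds$trait, " has no non-missing effect weights; ",
      "no summary can be computed",
      call. = FALSE
    )
  }
  single <- length(w) == 1L
  tibble::tibble(
    trait = ds$trait,
    n_files = ds$n_pgs,
    w_min = min(w),
    w_max = max(w),
    mean = mean(w),
    median = stats::median(w),
    sd = if (single) 0 else stats::sd(w),
    n_rows = length(w),
    single_obs = single
  )
}
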