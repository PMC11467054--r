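#' Canonical variant key for scoring-file records
#'
#' Every record is keyed by a single canonical string so that the same
#' variant labelled differently across scoring files collates together.
#' Precedence: harmonized rsID, then raw rsID, then harmonized
#' `chr:pos`, then raw `chr:pos`. rsIDs are lower-cased and given an `rs`
#' prefix if absent; chromosome labels are stripped of any `chr` prefix and
#' upper-cased (so `chr19 -> 19`, `x -> X`, `mt -> MT`). Coordinates stay
#' 1-based as distributed by the PGS Catalog.
#'
#' Note that an rsID-keyed and a coordinate-keyed occurrence of the same
#' physical variant are *not* unified: that would require an external
#' rsID-to-position map, so keys are taken at face value after
#' normalization.
#'
#' @param records A `pgs_scoring_file`, or a tibble of records with (some of)
#'   the columns `rsid`, `chr`, `pos`, `hm_rsid`, `hm_chr`, `hm_pos`.
#' @return Character vector of keys, one per record.
#' @examples
#' variant_key(tibble::tibble(rsid = "RS429358", chr = NA, pos = NA))
#' variant_key(tibble::tibble(rsid = NA, chr = "chr19", pos = 44908684))
#' @export
variant_key <- function(records) {
  if (inherits(records, "pgs_scoring_file")) records <- records$records
  n <- nrow(records)
  col <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  }
  key <- normalize_rsid(col("hm_rsid"))
  alt <- normalize_rsid(col("rsid"))
  key[is.na(key)] <- alt[is.na(key)]
  hm_coord <- coord_key(col("hm_chr"), col("hm_pos"))
  key[is.na(key)] <- hm_coord[is.na(key)]
  raw_coord <- coord_key(col("chr"), col("pos"))
  key[is.na(key)] <- raw_coord[is.na(key)]
  if (anyNA(key)) {
    stop(
      sum(is.na(key)), " record(s) carry no usable identifier ",
      "(rsID or chromosome+position)",
      call. = FALSE
    )
  }
  key
}

normalize_rsid <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  need_prefix <- !is.na(x) & !startsWith(x, "rs")
  x[need_prefix] <- paste0("rs", x[need_prefix])
  x
}

normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  toupper(x)
}

coord_key <- function(chr, pos) {
  out <- rep(NA_character_, length(chr))
  ok <- !is.na(chr) & !is.na(pos)
  out[ok] <- paste0(
    normalize_chrom(chr[ok]), ":",
    format(as.numeric(pos[ok]), scientific = FALSE, trim = TRUE)
  )
  out
}

# Normalize free-form variant identifiers (annotation tables): rsID-shaped
# strings go through rsID normalization, "chr:pos"-shaped through coordinate
# normalization, anything else is kept verbatim.
normalize_variant_id <- function(x) {
  x <- trimws(as.character(x))
  out <- x
  is_rs <- !is.na(x) & grepl("^[Rr][Ss][0-9]+$", x)
  out[is_rs] <- normalize_rsid(x[is_rs])
  is_coord <- !is.na(x) & grepl("^([Cc][Hh][Rr])?[0-9XYMTxymt]+:[0-9]+$", x)
  parts <- strsplit(x[is_coord], ":", fixed = TRUE)
  out[is_coord] <- vapply(
    parts,
    function(p) paste0(normalize_chrom(p[1]), ":", p[2]),
    character(1)
  )
  out
}

#' Merge a trait's scoring files into one dataset
#'
#' Concatenates the records of all scoring files mapped to one trait into a
#' single long table of `(pgs_id, variant_key, effect_weight)` rows -- the
#' `bind_rows` merge step of the rank-database build. No deduplication is
#' performed across files: each file is one ballot, and a variant occurring
#' in several files keeps one row per file. Within a single file a variant
#' key may only occur once; duplicate occurrences are resolved by keeping
#' the row with the largest absolute effect weight (a warning reports how
#' many rows were dropped). Rows with a missing weight are retained -- they
#' witness the variant's presence -- but are flagged and never ranked.
#'
#' @param trait Trait name (e.g. `"Alzheimer's disease"`).
#' @param files Non-empty list of `pgs_scoring_file` objects with distinct
#'   PGS accessions.
#' @return An object of class `pgs_trait_dataset`: a list with elements
#'   `trait`, `files`, `n_pgs`, and `merged_rows` (tibble with columns
#'   `pgs_id`, `variant_key`, `effect_weight`, `weight_missing`).
#' @export
merge_trait_files <- function(trait, files) {
  if (inherits(files, "pgs_scoring_file")) files <- list(files)
  if (length(files) == 0L) {
    stop("no scoring files supplied for trait ", trait, call. = FALSE)
  }
  ids <- vapply(files, function(f) f$pgs_id, character(1))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate PGS accession(s) in input: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      " (each score may be supplied once)",
      call. = FALSE
    )
  }

  per_file <- lapply(files, function(f) {
    tibble::tibble(
      pgs_id = f$pgs_id,
      variant_key = variant_key(f),
      effect_weight = f$records$effect_weight
    )
  })

  n_dropped <- 0L
  per_file <- lapply(per_file, function(rows) {
    if (!anyDuplicated(rows$variant_key)) return(rows)
    # one candidate, one position per ballot: keep the max-|w| occurrence
    # (missing weight loses to any value; ties keep the first occurrence)
    score <- abs(rows$effect_weight)
    score[is.na(score)] <- -Inf
    keep <- order(rows$variant_key, -score, seq_len(nrow(rows)))
    keep <- keep[!duplicated(rows$variant_key[keep])]
    n_dropped <<- n_dropped + (nrow(rows) - length(keep))
    rows[sort(keep), ]
  })
  if (n_dropped > 0L) {
    warning(
      n_dropped, " duplicate within-file variant occurrence(s) dropped ",
      "(kept the largest-|weight| row per variant and file)",
      call. = FALSE
    )
  }

  merged <- dplyr::bind_rows(per_file)
  merged$weight_missing <- is.na(merged$effect_weight)

  structure(
    list(
      trait = trait,
      files = files,
      n_pgs = length(files),
      merged_rows = merged
    ),
    class = "pgs_trait_dataset"
  )
}

#' @export
print.pgs_trait_dataset <- function(x, ...) {
  cat(
    "<pgs_trait_dataset> ", x$trait, ": ", x$n_pgs, " PGS file(s), ",
    nrow(x$merged_rows), " merged rows (",
    sum(x$merged_rows$weight_missing), " with missing weight)\n",
    sep = ""
  )
  invisible(x)
}
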