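#' Read a PGS Catalog harmonized scoring file
#'
#' Parses a scoring file as distributed by the PGS Catalog: `#key=value`
#' metadata header lines, followed by a tab-separated column-name row and one
#' data row per variant. Both plain and gzip-compressed files are read
#' transparently. Column-name dialects are tolerated: raw (`rsID`,
#' `chr_name`, `chr_position`) and harmonized (`hm_rsID`, `hm_chr`,
#' `hm_pos`) identifier columns are both recognized, and unknown extra
#' columns are carried through untouched. The missing-value tokens `"NA"`,
#' `""` and `"."` all parse to missing; on write only `"NA"` is emitted.
#'
#' Rows lacking any locatable identifier (an rsID, harmonized rsID, or a
#' chromosome+position pair), lacking an effect allele, or carrying a
#' non-positive position are rejected with a warning reporting the count;
#' the accepted records preserve file order.
#'
#' @param path Path to a scoring file (`.txt` or `.txt.gz`).
#' @param gzipped `"auto"` (default; decided by file content), `TRUE` or
#'   `FALSE`. Only used to pick the connection type; `gzfile()` reads plain
#'   text transparently, so `"auto"` always works.
#' @return An object of class `pgs_scoring_file`: a list with elements
#'   `pgs_id`, `trait_label`, `genome_build`, `metadata` (named list of all
#'   header keys), `records` (a tibble, one row per accepted variant),
#'   `n_rejected`, and `source_path`.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines(c(
#'   "#pgs_id=PGS000001", "#genome_build=GRCh38",
#'   "rsID\teffect_allele\teffect_weight",
#'   "rs111\tA\t0.5", "rs222\tG\tNA"
#' ), p)
#' sf <- read_scoring_file(p)
#' sf$records$effect_weight  # 0.5 NA
#' @export
read_scoring_file <- function(path, gzipped = "auto") {
  if (!file.exists(path)) {
    stop("scoring file not found: ", path, call. = FALSE)
  }
  con <- if (isFALSE(gzipped)) file(path, "r") else gzfile(path, "r")
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))

  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta_lines <- lines[seq_len(n_meta)]
  body <- lines[-seq_len(n_meta)]
  body <- body[nzchar(body)]

  metadata <- parse_metadata(meta_lines)

  if (length(body) < 1L) {
    stop("scoring file has no column-name row: ", path, call. = FALSE)
  }
  if (length(body) < 2L) {
    stop("scoring file has an empty data section: ", path, call. = FALSE)
  }

  raw <- readr::read_tsv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (nrow(raw) == 0L) {
    stop("scoring file has an empty data section: ", path, call. = FALSE)
  }

  cmap <- match_columns(names(raw))
  if (is.na(cmap[["effect_weight"]])) {
    stop("scoring file lacks an effect_weight column: ", path, call. = FALSE)
  }
  if (is.na(cmap[["effect_allele"]])) {
    stop("scoring file lacks an effect_allele column: ", path, call. = FALSE)
  }

  take <- function(field) {
    idx <- cmap[[field]]
    if (is.na(idx)) rep(NA_character_, nrow(raw)) else blank_to_na(raw[[idx]])
  }

  weight_text <- take("effect_weight")
  weight <- suppressWarnings(as.numeric(weight_text))
  bad <- which(!is.na(weight_text) & is.na(weight))
  if (length(bad) > 0L) {
    stop(
      "unparseable effect_weight at data row(s) ",
      paste(utils::head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) ", ..." else "",
      " in ", path,
      call. = FALSE
    )
  }

  records <- tibble::tibble(
    rsid = take("rsid"),
    chr = take("chr"),
    pos = suppressWarnings(as.numeric(take("pos"))),
    effect_allele = take("effect_allele"),
    other_allele = take("other_allele"),
    effect_weight = weight,
    effect_weight_text = weight_text,
    hm_rsid = take("hm_rsid"),
    hm_chr = take("hm_chr"),
    hm_pos = suppressWarnings(as.numeric(take("hm_pos")))
  )
  extra <- raw[setdiff(seq_along(raw), stats::na.omit(unname(cmap)))]
  if (ncol(extra) > 0L) {
    records <- dplyr::bind_cols(records, extra)
  }

  locatable <- !is.na(records$rsid) | !is.na(records$hm_rsid) |
    (!is.na(records$chr) & !is.na(records$pos)) |
    (!is.na(records$hm_chr) & !is.na(records$hm_pos))
  pos_ok <- (is.na(records$pos) | records$pos >= 1) &
    (is.na(records$hm_pos) | records$hm_pos >= 1)
  ok <- locatable & pos_ok & !is.na(records$effect_allele)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    warning(
      n_rejected, " record(s) rejected (no locatable identifier, missing ",
      "effect allele, or invalid position) in ", path,
      call. = FALSE
    )
    records <- records[ok, ]
  }
  if (nrow(records) == 0L) {
    stop("no valid records in scoring file: ", path, call. = FALSE)
  }

  pgs_id <- metadata[["pgs_id"]]
  if (is.null(pgs_id) || !grepl("^PGS[0-9]{6}$", pgs_id)) {
    stop(
      "missing or malformed #pgs_id header (expected PGS followed by six ",
      "digits) in ", path,
      call. = FALSE
    )
  }

  structure(
    list(
      pgs_id = pgs_id,
      trait_label = metadata[["trait_reported"]] %||%
        metadata[["trait_mapped"]] %||% NA_character_,
      genome_build = metadata[["HmPOS_build"]] %||%
        metadata[["genome_build"]] %||% NA_character_,
      metadata = metadata,
      records = records,
      n_rejected = n_rejected,
      source_path = path
    ),
    class = "pgs_scoring_file"
  )
}

parse_metadata <- function(meta_lines) {
  txt <- sub("^#+\\s*", "", meta_lines)
  txt <- txt[grepl("=", txt, fixed = TRUE)]
  keys <- sub("=.*$", "", txt)
  vals <- sub("^[^=]*=", "", txt)
  stats::setNames(as.list(vals), trimws(keys))
}

# Column-name dialect table: canonical field -> accepted headers
# (matched case-insensitively; first hit wins).
scoring_column_dialects <- list(
  rsid = c("rsID", "rsid", "SNP"),
  chr = c("chr_name", "chr", "chromosome"),
  pos = c("chr_position", "pos", "position", "bp"),
  effect_allele = c("effect_allele", "A1"),
  other_allele = c("other_allele", "reference_allele", "A2"),
  effect_weight = c("effect_weight", "weight", "beta"),
  hm_rsid = c("hm_rsID", "hm_rsid"),
  hm_chr = "hm_chr",
  hm_pos = "hm_pos"
)

match_columns <- function(nms) {
  lower <- tolower(nms)
  taken <- integer(0)
  out <- vapply(scoring_column_dialects, function(aliases) {
    for (a in tolower(aliases)) {
      hit <- match(a, lower)
      if (!is.na(hit) && !(hit %in% taken)) {
        taken <<- c(taken, hit)
        return(hit)
      }
    }
    NA_integer_
  }, integer(1))
  out
}

blank_to_na <- function(x) {
  x[x %in% c("NA", "", ".")] <- NA_character_
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pgs_scoring_file <- function(x, ...) {
  cat(
    "<pgs_scoring_file> ", x$pgs_id,
    " (", x$genome_build, "), ", nrow(x$records), " records",
    if (!is.na(x$trait_label)) paste0(", trait: ", x$trait_label) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a scoring file in PGS Catalog format
#'
#' Serializes a `pgs_scoring_file` back to disk: `#key=value` metadata header,
#' tab-separated column row, one row per record. Missing cells are written as
#' `"NA"`, so `read_scoring_file(write_scoring_file(sf, p))` reproduces the
#' records field-for-field. Effect weights are written from the retained
#' original text where available, otherwise with 17 significant digits so the
#' parsed double survives the round trip.
#'
#' @param sf A `pgs_scoring_file` (or a list with `pgs_id`, `genome_build`,
#'   `metadata` and a `records` tibble).
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(sf, path) {
  records <- sf$records
  if (is.null(records) || nrow(records) == 0L) {
    stop("refusing to write a scoring file with zero records", call. = FALSE)
  }
  meta <- sf$metadata %||% list()
  meta[["pgs_id"]] <- sf$pgs_id
  if (!is.null(sf$genome_build) && !is.na(sf$genome_build)) {
    meta[["genome_build"]] <- sf$genome_build
  }
  if (!is.null(sf$trait_label) && !is.na(sf$trait_label)) {
    meta[["trait_reported"]] <- sf$trait_label
  }

  wt <- records$effect_weight
  wt_text <- if ("effect_weight_text" %in% names(records)) {
    records$effect_weight_text
  } else {
    rep(NA_character_, nrow(records))
  }
  need <- is.na(wt_text) & !is.na(wt)
  wt_text[need] <- sprintf("%.17g", wt[need])

  out <- tibble::tibble(
    rsID = records$rsid,
    chr_name = records$chr,
    chr_position = fmt_pos(records$pos),
    effect_allele = records$effect_allele,
    other_allele = records$other_allele,
    effect_weight = wt_text,
    hm_rsID = records$hm_rsid,
    hm_chr = records$hm_chr,
    hm_pos = fmt_pos(records$hm_pos)
  )
  extra_nms <- setdiff(
    names(records),
    c("rsid", "chr", "pos", "effect_allele", "other_allele",
      "effect_weight", "effect_weight_text", "hm_rsid", "hm_chr", "hm_pos")
  )
  for (nm in extra_nms) out[[nm]] <- as.character(records[[nm]])
  for (nm in names(out)) out[[nm]][is.na(out[[nm]])] <- "NA"

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("#", names(meta), "=", unlist(meta)), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

fmt_pos <- function(p) {
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- format(p[!is.na(p)], scientific = FALSE, trim = TRUE)
  out
}

#' Load a variant-to-gene annotation table
#'
#' Reads a tab-separated annotation table in the style of ANNOVAR multianno
#' output: one row per variant-gene assignment, with columns for the variant
#' identifier (rsID or `chr:pos`), the gene symbol, and the functional
#' category. Column headers are matched case-insensitively against common
#' dialects. Variant identifiers are normalized with the same rules as
#' [variant_key()] so annotation keys join against rank-table keys. A variant
#' may map to several genes; all assignments are retained. Exact duplicate
#' rows are dropped silently with a reported count.
#'
#' @param path Path to the tab-separated annotation table.
#' @return A tibble with columns `variant_key`, `gene`, `category`.
#' @export
load_annotation_table <- function(path) {
  if (!file.exists(path)) {
    stop("annotation table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", "", "."), progress = FALSE
  )
  lower <- tolower(names(raw))
  pick <- function(aliases) {
    for (a in aliases) {
      hit <- match(a, lower)
      if (!is.na(hit)) return(hit)
    }
    NA_integer_
  }
  vi <- pick(c("variant", "variant_key", "rsid", "snp", "avsnp150", "id"))
  gi <- pick(c("gene", "gene.refgene", "gene_refgene", "gene_symbol", "genes"))
  ci <- pick(c(
    "func", "func.refgene", "func_refgene", "function",
    "category", "functional_category"
  ))
  missing_cols <- c(
    if (is.na(vi)) "variant identifier",
    if (is.na(gi)) "gene symbol",
    if (is.na(ci)) "functional category"
  )
  if (length(missing_cols) > 0L) {
    stop(
      "annotation table lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    variant_key = normalize_variant_id(raw[[vi]]),
    gene = raw[[gi]],
    category = raw[[ci]]
  )
  out <- out[!is.na(out$variant_key) & !is.na(out$gene), ]
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n0) {
    message(n0 - nrow(out), " duplicate annotation row(s) dropped")
  }
  out
}
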