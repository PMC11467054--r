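#' Build the variant/gene rank database
#'
#' Materializes one or more trait datasets and their derived tables into a
#' single SQLite file with five tables: `traits(trait)`,
#' `scores(pgs_id, trait, n_variants)`,
#' `variant_ranks(trait, variant_key, mrr, n_present, n_pgs)`,
#' `gene_ranks(trait, gene, score, n_variants, best_variant)` and
#' `summary(trait, n_files, w_min, w_max, mean, median, sd, n_rows)`.
#' Primary-key and foreign-key constraints enforce referential integrity;
#' the build is atomic (written to a temporary file, moved into place on
#' success, removed on failure) and rebuilding from identical inputs gives
#' identical query results. The schema version is stored in the SQLite
#' `user_version` pragma.
#'
#' @param datasets A `pgs_trait_dataset` or list of them (one per trait).
#' @param ranks Variant rank tibble ([aggregate_mrr()] output, traits
#'   row-bound together).
#' @param gene_ranks Optional gene rank tibble ([gene_scores()] output).
#' @param summaries Optional summary tibble ([trait_summary()] output).
#' @param path Output path of the database file.
#' @param overwrite Overwrite an existing file at `path`? Default `FALSE`.
#' @return A `pgs_rank_db` handle (see [rank_db()]).
#' @export
build_rank_db <- function(datasets, ranks, gene_ranks = NULL,
                          summaries = NULL, path, overwrite = FALSE) {
  if (inherits(datasets, "pgs_trait_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  if (file.exists(path) && !overwrite) {
    stop(
      "database file already exists: ", path,
      " (use overwrite = TRUE to replace it)",
      call. = FALSE
    )
  }

  traits_tbl <- tibble::tibble(
    trait = vapply(datasets, function(d) d$trait, character(1))
  )
  scores_tbl <- dplyr::bind_rows(lapply(datasets, function(d) {
    tibble::tibble(
      pgs_id = vapply(d$files, function(f) f$pgs_id, character(1)),
      trait = d$trait,
      n_variants = as.integer(table(
        factor(d$merged_rows$pgs_id,
               levels = vapply(d$files, function(f) f$pgs_id, character(1)))
      ))
    )
  }))

  tmp <- paste0(path, ".build.tmp")
  if (file.exists(tmp)) unlink(tmp)
  con <- DBI::dbConnect(RSQLite::SQLite(), tmp)
  ok <- FALSE
  on.exit({
    DBI::dbDisconnect(con)
    if (!ok && file.exists(tmp)) unlink(tmp)
  })

  DBI::dbExecute(con, "PRAGMA user_version = 1")
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  DBI::dbExecute(con, "CREATE TABLE traits (trait TEXT PRIMARY KEY)")
  DBI::dbExecute(con, "
    CREATE TABLE scores (
      pgs_id TEXT NOT NULL,
      trait TEXT NOT NULL REFERENCES traits(trait),
      n_variants INTEGER NOT NULL,
      PRIMARY KEY (pgs_id, trait)
    )")
  DBI::dbExecute(con, "
    CREATE TABLE variant_ranks (
      trait TEXT NOT NULL REFERENCES traits(trait),
      variant_key TEXT NOT NULL,
      mrr REAL NOT NULL CHECK (mrr >= 0 AND mrr <= 1),
      n_present INTEGER NOT NULL,
      n_pgs INTEGER NOT NULL,
      PRIMARY KEY (trait, variant_key)
    )")
  DBI::dbExecute(con, "
    CREATE TABLE gene_ranks (
      trait TEXT NOT NULL REFERENCES traits(trait),
      gene TEXT NOT NULL,
      score REAL NOT NULL CHECK (score >= 0 AND score <= 1),
      n_variants INTEGER NOT NULL,
      best_variant TEXT NOT NULL,
      PRIMARY KEY (trait, gene)
    )")
  DBI::dbExecute(con, "
    CREATE TABLE summary (
      trait TEXT PRIMARY KEY REFERENCES traits(trait),
      n_files INTEGER NOT NULL,
      w_min REAL NOT NULL,
      w_max REAL NOT NULL,
      mean REAL NOT NULL,
      median REAL NOT NULL,
      sd REAL NOT NULL,
      n_rows INTEGER NOT NULL
    )")

  append <- function(tbl, df, cols) {
    if (is.null(df) || nrow(df) == 0L) return(invisible())
    DBI::dbAppendTable(con, tbl, as.data.frame(df[, cols]))
  }
  tryCatch({
    append("traits", traits_tbl, "trait")
    append("scores", scores_tbl, c("pgs_id", "trait", "n_variants"))
    append(
      "variant_ranks", ranks,
      c("trait", "variant_key", "mrr", "n_present", "n_pgs")
    )
    append(
      "gene_ranks", gene_ranks,
      c("trait", "gene", "score", "n_variants", "best_variant")
    )
    append(
      "summary", summaries,
      c("trait", "n_files", "w_min", "w_max", "mean", "median", "sd", "n_rows")
    )
  }, error = function(e) {
    stop("database build aborted: ", conditionMessage(e), call. = FALSE)
  })

  DBI::dbDisconnect(con)
  on.exit()
  if (file.exists(path)) unlink(path)
  if (!file.rename(tmp, path)) {
    # rename can fail across filesystems; fall back to copy + delete
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  rank_db(path)
}

#' Open a rank database handle
#'
#' A lightweight handle around the database file path. Query functions open
#' a read-only connection per call, so results are a pure function of the
#' file on disk.
#'
#' @param path Path to an existing rank database file.
#' @return An object of class `pgs_rank_db`.
#' @export
rank_db <- function(path) {
  if (!file.exists(path)) {
    stop("rank database not found: ", path, call. = FALSE)
  }
  structure(list(path = path), class = "pgs_rank_db")
}

#' @export
print.pgs_rank_db <- function(x, ...) {
  con <- db_connect(x)
  on.exit(DBI::dbDisconnect(con))
  traits <- DBI::dbGetQuery(con, "SELECT trait FROM traits ORDER BY trait")$trait
  nv <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM variant_ranks")$n
  ng <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM gene_ranks")$n
  cat(
    "<pgs_rank_db> ", x$path, "\n  traits: ",
    paste(traits, collapse = ", "), "\n  ",
    nv, " variant rank(s), ", ng, " gene rank(s)\n",
    sep = ""
  )
  invisible(x)
}

db_connect <- function(db) {
  stopifnot(inherits(db, "pgs_rank_db"))
  DBI::dbConnect(RSQLite::SQLite(), db$path, flags = RSQLite::SQLITE_RO)
}

# Trait names are stored verbatim but matched case-insensitively, with a
# substring fallback so e.g. "Alzheimer" resolves to "Alzheimer's disease".
resolve_trait <- function(con, trait) {
  known <- DBI::dbGetQuery(con, "SELECT trait FROM traits ORDER BY trait")$trait
  hit <- known[tolower(known) == tolower(trait)]
  if (length(hit) == 0L) {
    hit <- known[grepl(tolower(trait), tolower(known), fixed = TRUE)]
  }
  if (length(hit) == 0L) {
    stop(
      "unknown trait '", trait, "'; available traits: ",
      paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(hit) > 1L) {
    stop(
      "trait '", trait, "' is ambiguous; matches: ",
      paste(hit, collapse = ", "),
      call. = FALSE
    )
  }
  hit
}

#' Top-ranked variants for a trait
#'
#' Returns the trait's `n` highest-MRR variants, ordered by `mrr` descending
#' with ties broken by `variant_key` ascending (so "top N" queries are
#' reproducible). Fewer than `n` rows are returned when the trait has fewer
#' variants. The trait is matched case-insensitively with a substring
#' fallback; an unknown trait raises an error listing the available traits.
#'
#' @param db A `pgs_rank_db` handle (or a path).
#' @param trait Trait name or unambiguous fragment.
#' @param n Maximum number of rows, at least 1.
#' @return Tibble with columns `trait`, `variant_key`, `mrr`, `n_present`,
#'   `n_pgs`.
#' @export
query_top_variants <- function(db, trait, n = 10L) {
  if (is.character(db)) db <- rank_db(db)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  t <- resolve_trait(con, trait)
  res <- DBI::dbGetQuery(
    con,
    "SELECT trait, variant_key, mrr, n_present, n_pgs FROM variant_ranks
     WHERE trait = ? ORDER BY mrr DESC, variant_key ASC LIMIT ?",
    params = list(t, as.integer(n))
  )
  tibble::as_tibble(res)
}

#' Top-ranked genes for a trait
#'
#' As [query_top_variants()], over the gene rollup table. Gene symbols are
#' unique per trait by construction, so each gene appears at most once.
#'
#' @inheritParams query_top_variants
#' @return Tibble with columns `trait`, `gene`, `score`, `n_variants`,
#'   `best_variant`.
#' @export
query_top_genes <- function(db, trait, n = 10L) {
  if (is.character(db)) db <- rank_db(db)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  t <- resolve_trait(con, trait)
  res <- DBI::dbGetQuery(
    con,
    "SELECT trait, gene, score, n_variants, best_variant FROM gene_ranks
     WHERE trait = ? ORDER BY score DESC, gene ASC LIMIT ?",
    params = list(t, as.integer(n))
  )
  tibble::as_tibble(res)
}

#' Per-trait weight summary rows from the database
#'
#' @param db A `pgs_rank_db` handle (or a path).
#' @param trait Optional trait name or fragment; all traits when `NULL`.
#' @return Tibble with one row per trait: `trait`, `n_files`, `w_min`,
#'   `w_max`, `mean`, `median`, `sd`, `n_rows`.
#' @export
query_trait_summary <- function(db, trait = NULL) {
  if (is.character(db)) db <- rank_db(db)
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  if (is.null(trait)) {
    res <- DBI::dbGetQuery(con, "SELECT * FROM summary ORDER BY trait")
  } else {
    t <- resolve_trait(con, trait)
    res <- DBI::dbGetQuery(
      con, "SELECT * FROM summary WHERE trait = ?", params = list(t)
    )
  }
  tibble::as_tibble(res)
}

#' Check referential integrity of a rank database
#'
#' Verifies, over all tables, that every `trait` referenced by `scores`,
#' `variant_ranks`, `gene_ranks` and `summary` exists in `traits`, that
#' `(trait, variant_key)` and `(trait, gene)` are unique, and that all MRR
#' and gene scores lie in \[0, 1\].
#'
#' @param db A `pgs_rank_db` handle (or a path).
#' @return Character vector of violation descriptions; empty when the
#'   database is consistent.
#' @export
db_integrity_check <- function(db) {
  if (is.character(db)) db <- rank_db(db)
  con <- db_connect(db)
  on.exit(DBI::dbDisconnect(con))
  q <- function(sql) DBI::dbGetQuery(con, sql)$n
  checks <- c(
    "scores references a missing trait" = q(
      "SELECT COUNT(*) AS n FROM scores
       WHERE trait NOT IN (SELECT trait FROM traits)"
    ),
    "variant_ranks references a missing trait" = q(
      "SELECT COUNT(*) AS n FROM variant_ranks
       WHERE trait NOT IN (SELECT trait FROM traits)"
    ),
    "gene_ranks references a missing trait" = q(
      "SELECT COUNT(*) AS n FROM gene_ranks
       WHERE trait NOT IN (SELECT trait FROM traits)"
    ),
    "summary references a missing trait" = q(
      "SELECT COUNT(*) AS n FROM summary
       WHERE trait NOT IN (SELECT trait FROM traits)"
    ),
    "duplicate (trait, variant_key)" = q(
      "SELECT COUNT(*) AS n FROM (SELECT trait, variant_key
       FROM variant_ranks GROUP BY trait, variant_key HAVING COUNT(*) > 1)"
    ),
    "duplicate (trait, gene)" = q(
      "SELECT COUNT(*) AS n FROM (SELECT trait, gene
       FROM gene_ranks GROUP BY trait, gene HAVING COUNT(*) > 1)"
    ),
    "mrr outside [0, 1]" = q(
      "SELECT COUNT(*) AS n FROM variant_ranks WHERE mrr < 0 OR mrr > 1"
    ),
    "gene score outside [0, 1]" = q(
      "SELECT COUNT(*) AS n FROM gene_ranks WHERE score < 0 OR score > 1"
    )
  )
  bad <- checks[checks > 0]
  if (length(bad) == 0L) character(0) else
    paste0(names(bad), " (", bad, " row(s))")
}
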