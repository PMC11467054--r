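#' Discover PGS accessions mapped to a trait
#'
#' Queries the PGS Catalog REST API (`/rest/score/search?trait=...`) for the
#' scores mapped to a trait term and filters them to those released on or
#' before `release_cutoff`, so a historical catalog state can be
#' approximated from the live API (the API serves current state only, so
#' the reproduction is best-effort). Results are cached on disk keyed by
#' `(trait, cutoff)`; a repeated call is served from the cache without
#' touching the network.
#'
#' The HTTP layer is injectable: `transport` is a function taking a URL and
#' returning the parsed JSON payload as a list, which keeps every unit test
#' offline. The default transport fetches and parses the URL with
#' `jsonlite`.
#'
#' @param trait_term Trait label or EFO accession (e.g. `"EFO_0000249"`).
#' @param release_cutoff Keep only scores with `date_release` on or before
#'   this date (default `"2023-08-04"`).
#' @param cache_dir Optional directory for the on-disk response cache.
#' @param transport Function `function(url) -> list`; defaults to a live
#'   HTTPS fetch.
#' @return Character vector of PGS accessions (possibly empty, with a
#'   warning, when the trait is unknown).
#' @export
pgs_score_ids <- function(trait_term, release_cutoff = "2023-08-04",
                          cache_dir = NULL, transport = NULL) {
  cutoff <- as.Date(release_cutoff)
  if (is.na(cutoff)) stop("invalid release_cutoff date", call. = FALSE)

  cache_file <- NULL
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    cache_file <- file.path(cache_dir, paste0(
      "scores_", gsub("[^A-Za-z0-9]+", "_", trait_term), "_",
      format(cutoff), ".json"
    ))
    if (file.exists(cache_file)) {
      return(unlist(jsonlite::read_json(cache_file), use.names = FALSE))
    }
  }

  if (is.null(transport)) transport <- default_transport
  url <- paste0(
    "https://www.pgscatalog.org/rest/score/search?trait=",
    utils::URLencode(trait_term, reserved = TRUE), "&limit=100"
  )
  results <- list()
  while (!is.null(url)) {
    page <- tryCatch(transport(url), error = function(e) {
      stop(
        errorCondition(
          paste0("PGS Catalog request failed (retriable): ",
                 conditionMessage(e)),
          class = c("pgsrank_network_error", "error")
        )
      )
    })
    results <- c(results, page$results)
    url <- page[["next"]]
    if (is.null(url) || identical(url, "")) url <- NULL
  }

  if (length(results) == 0L) {
    warning("no scores found for trait term '", trait_term, "'",
            call. = FALSE)
    ids <- character(0)
  } else {
    dates <- vapply(results, function(r) {
      d <- r[["date_release"]]
      if (is.null(d)) NA_character_ else as.character(d)
    }, character(1))
    keep <- !is.na(dates) & as.Date(dates) <= cutoff
    ids <- vapply(results[keep], function(r) r[["id"]], character(1))
    ids <- sort(unique(ids))
  }

  if (!is.null(cache_file)) {
    jsonlite::write_json(ids, cache_file)
  }
  ids
}

default_transport <- function(url) {
  jsonlite::fromJSON(url, simplifyVector = FALSE)
}

#' Download harmonized GRCh38 scoring files for a set of accessions
#'
#' Fetches each accession's harmonized GRCh38 scoring file from the PGS
#' Catalog download area into `outdir`, skipping accessions whose file is
#' already present (and non-empty) on disk. A failed download (e.g. an
#' accession without a harmonized file) produces a warning for that
#' accession; the others proceed. The MD5 of each fetched file is reported
#' for provenance.
#'
#' @param ids Character vector of PGS accessions.
#' @param outdir Download directory (created if needed).
#' @param download_fun Function `function(url, destfile)` performing the
#'   download; defaults to [utils::download.file()]. Injectable for
#'   offline tests.
#' @return Named character vector of local paths (one per successfully
#'   available accession).
#' @export
pgs_fetch_scoring_files <- function(ids, outdir, download_fun = NULL) {
  if (length(ids) == 0L) return(stats::setNames(character(0), character(0)))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(download_fun)) {
    download_fun <- function(url, destfile) {
      utils::download.file(url, destfile, mode = "wb", quiet = TRUE)
    }
  }
  out <- character(0)
  for (id in ids) {
    dest <- file.path(outdir, paste0(id, "_hmPOS_GRCh38.txt.gz"))
    if (file.exists(dest) && file.size(dest) > 0) {
      message(id, ": using existing local copy")
      out[id] <- dest
      next
    }
    url <- paste0(
      "https://ftp.ebi.ac.uk/pub/databases/spot/pgs/scores/", id,
      "/ScoringFiles/Harmonized/", id, "_hmPOS_GRCh38.txt.gz"
    )
    got <- tryCatch({
      download_fun(url, dest)
      TRUE
    }, error = function(e) {
      warning(
        id, ": harmonized scoring file unavailable (",
        conditionMessage(e), ")",
        call. = FALSE
      )
      FALSE
    })
    if (got && file.exists(dest) && file.size(dest) > 0) {
      message(id, ": fetched, md5 ", unname(tools::md5sum(dest)))
      out[id] <- dest
    } else if (file.exists(dest) && file.size(dest) == 0) {
      unlink(dest)
    }
  }
  out
}
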