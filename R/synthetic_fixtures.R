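#' Specify a synthetic scoring-file corpus
#'
#' Describes a fully seeded synthetic trait: several scoring files with a
#' partially shared variant pool, signed effect weights whose magnitudes
#' span several orders (a per-file scale factor on a common normal spread,
#' so tiny scientific-notation weights and order-1 weights coexist the way
#' they do in real score sets), a fraction of weights masked to `"NA"`, and
#' a mix of rsID-keyed and coordinate-keyed variants written in varying
#' label dialects (upper-case `RS`, `chr`-prefixed chromosomes) to exercise
#' key normalization. Optionally a chosen variant is planted with the
#' strictly largest |weight| in every file, giving it a known MRR of 1.
#'
#' Defaults describe the conditions the package is validated under: 5 files
#' of 200 variants, half drawn from a pool shared by every file, weight
#' spread 0.04 with per-file scales in \[0.1, 10\], 10% missing weights and
#' 30% coordinate-keyed variants.
#'
#' @param n_files Number of scoring files (>= 1).
#' @param n_variants_per_file Variants per file (>= 1).
#' @param overlap Fraction in \[0, 1\] of each file's variants drawn from a
#'   pool present in every file; `1` makes all key sets identical.
#' @param weight_sd Standard deviation of the base normal weight draw.
#' @param scale_range Length-2 positive range; each file's weights are
#'   multiplied by a log-uniform draw from it.
#' @param missing_rate Fraction of weights replaced by `"NA"`.
#' @param coordinate_fraction Fraction of variants keyed by `chr:pos`
#'   instead of rsID.
#' @param planted_top Optional variant key (e.g. `"rs999"`) forced to carry
#'   the largest |weight| in every file, never missing.
#' @param seed Integer seed; the same spec yields a byte-identical corpus.
#' @param trait Trait label written into the files.
#' @param pgs_id_start First synthetic accession number.
#' @return An object of class `pgs_fixture_spec`.
#' @export
fixture_spec <- function(n_files = 5L, n_variants_per_file = 200L,
                         overlap = 0.5, weight_sd = 0.04,
                         scale_range = c(0.1, 10), missing_rate = 0.1,
                         coordinate_fraction = 0.3, planted_top = NULL,
                         seed = 1L, trait = "synthetic trait",
                         pgs_id_start = 900001L) {
  stopifnot(
    n_files >= 1L, n_variants_per_file >= 1L,
    overlap >= 0, overlap <= 1,
    missing_rate >= 0, missing_rate <= 1,
    coordinate_fraction >= 0, coordinate_fraction <= 1,
    weight_sd > 0, length(scale_range) == 2L, all(scale_range > 0),
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(
      n_files = as.integer(n_files),
      n_variants_per_file = as.integer(n_variants_per_file),
      overlap = overlap,
      weight_sd = weight_sd,
      scale_range = as.numeric(scale_range),
      missing_rate = missing_rate,
      coordinate_fraction = coordinate_fraction,
      planted_top = planted_top,
      seed = as.integer(seed),
      trait = trait,
      pgs_id_start = as.integer(pgs_id_start)
    ),
    class = "pgs_fixture_spec"
  )
}

# Independent per-file random streams: file i's seed is a pure function of
# (corpus seed, i), so adding a file never perturbs earlier files.
stream_seed <- function(seed, i) {
  as.integer(((as.double(seed) + 1) * 48271 + i * 2654435761) %% 2147483629) + 1L
}

# Deterministic unique variant identities: shared pool and each file's
# private block live in disjoint integer ranges, so keys never collide.
make_pool_variants <- function(numbers, coordinate_fraction) {
  is_coord <- stats::runif(length(numbers)) < coordinate_fraction
  tibble::tibble(
    number = numbers,
    is_coord = is_coord,
    chr = as.character(numbers %% 22L + 1L),
    pos = as.numeric(numbers),
    key = ifelse(
      is_coord,
      paste0(numbers %% 22L + 1L, ":", numbers),
      paste0("rs", numbers)
    )
  )
}

#' Generate a synthetic scoring-file corpus with known ground truth
#'
#' Writes `n_files` parseable gzipped scoring files to `outdir` plus a
#' manifest recording every true weight and canonical key, so downstream
#' modules can be validated against an independent recomputation
#' ([oracle_mrr()]). Deterministic: the same spec (including seed) produces
#' byte-identical files.
#'
#' @param spec A `pgs_fixture_spec`.
#' @param outdir Output directory (created if needed).
#' @param manifest_path Optional path; when given, the manifest is also
#'   written there as JSON.
#' @return List with elements `paths` (character vector of scoring-file
#'   paths) and `manifest` (list: `trait`, `n_files`, `planted_top`,
#'   `files` -- per file `pgs_id`, `path`, `key`, `weight` with `NA` for
#'   masked weights).
#' @export
generate_corpus <- function(spec, outdir, manifest_path = NULL) {
  stopifnot(inherits(spec, "pgs_fixture_spec"))
  if (!dir.exists(outdir)) {
    if (!dir.create(outdir, recursive = TRUE)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
  }
  n <- spec$n_variants_per_file
  n_shared <- round(spec$overlap * n)
  n_private <- n - n_shared

  set.seed(stream_seed(spec$seed, 0L))
  shared_numbers <- sample.int(10000000L, n_shared) + 900000000L
  shared <- make_pool_variants(shared_numbers, spec$coordinate_fraction)

  planted_key <- spec$planted_top
  planted_row <- NULL
  if (!is.null(planted_key)) {
    if (grepl(":", planted_key, fixed = TRUE)) {
      p <- strsplit(planted_key, ":", fixed = TRUE)[[1]]
      planted_row <- tibble::tibble(
        number = NA_real_, is_coord = TRUE, chr = p[1],
        pos = as.numeric(p[2]), key = planted_key
      )
    } else {
      planted_row <- tibble::tibble(
        number = NA_real_, is_coord = FALSE, chr = NA_character_,
        pos = NA_real_, key = planted_key
      )
    }
    shared <- shared[shared$key != planted_key, ]
  }

  paths <- character(spec$n_files)
  manifest_files <- vector("list", spec$n_files)
  alleles <- c("A", "C", "G", "T")

  for (i in seq_len(spec$n_files)) {
    set.seed(stream_seed(spec$seed, i))
    private_numbers <- if (n_private > 0L) {
      sample.int(10000000L, n_private) + i * 10000000L
    } else {
      integer(0)
    }
    private <- make_pool_variants(private_numbers, spec$coordinate_fraction)
    vars <- rbind(shared, private)
    if (!is.null(planted_row)) vars <- rbind(planted_row, vars)
    vars <- vars[sample.int(nrow(vars)), ]

    scale_i <- exp(stats::runif(
      1, log(spec$scale_range[1]), log(spec$scale_range[2])
    ))
    w <- stats::rnorm(nrow(vars), 0, spec$weight_sd) * scale_i
    missing <- stats::runif(nrow(vars)) < spec$missing_rate

    is_planted <- !is.null(planted_key) & vars$key == planted_key
    if (any(is_planted)) {
      missing[is_planted] <- FALSE
      w[is_planted] <- (max(abs(w[!is_planted]), 0) + 1) * 2
    }

    # vary the written label dialect to exercise key normalization
    rs_label <- sub("^rs", "", vars$key)
    upper <- stats::runif(nrow(vars)) < 0.3
    rs_label <- ifelse(upper, paste0("RS", rs_label), paste0("rs", rs_label))
    chr_label <- ifelse(
      stats::runif(nrow(vars)) < 0.3, paste0("chr", vars$chr), vars$chr
    )

    ea <- sample(alleles, nrow(vars), replace = TRUE)
    oa <- vapply(
      ea, function(a) sample(setdiff(alleles, a), 1), character(1)
    )

    records <- tibble::tibble(
      rsid = ifelse(vars$is_coord, NA_character_, rs_label),
      chr = ifelse(vars$is_coord, chr_label, NA_character_),
      pos = ifelse(vars$is_coord, vars$pos, NA_real_),
      effect_allele = ea,
      other_allele = oa,
      effect_weight = ifelse(missing, NA_real_, w),
      hm_rsid = ifelse(vars$is_coord, NA_character_, rs_label),
      hm_chr = ifelse(vars$is_coord, chr_label, NA_character_),
      hm_pos = ifelse(vars$is_coord, vars$pos, NA_real_)
    )

    pgs_id <- sprintf("PGS%06d", spec$pgs_id_start + i - 1L)
    path <- file.path(outdir, paste0(pgs_id, "_hmPOS_GRCh38.txt.gz"))
    sf <- structure(
      list(
        pgs_id = pgs_id, trait_label = spec$trait,
        genome_build = "GRCh38",
        metadata = list(
          pgs_id = pgs_id, genome_build = "GRCh38",
          trait_reported = spec$trait, synthetic = "true"
        ),
        records = records, n_rejected = 0L, source_path = NA_character_
      ),
      class = "pgs_scoring_file"
    )
    write_scoring_file(sf, path)

    paths[i] <- path
    manifest_files[[i]] <- list(
      pgs_id = pgs_id,
      path = path,
      key = vars$key,
      weight = ifelse(missing, NA_real_, w)
    )
  }

  manifest <- list(
    trait = spec$trait,
    n_files = spec$n_files,
    planted_top = planted_key,
    spec = unclass(spec),
    files = manifest_files
  )
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      manifest, manifest_path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
  }
  list(paths = paths, manifest = manifest)
}

#' Brute-force MRR oracle from a corpus manifest
#'
#' Recomputes every variant's mean reciprocal rank directly from the
#' manifest's true weights -- re-sorting, re-assigning reciprocal ranks and
#' re-averaging from scratch, sharing no code with [rank_within_pgs()] or
#' [aggregate_mrr()] -- for use as an independent cross-check of the full
#' parse/merge/rank pipeline.
#'
#' @param manifest Manifest list from [generate_corpus()].
#' @param denominator `"all_files"` (default) or `"files_present"`, matching
#'   [aggregate_mrr()].
#' @return Named numeric vector: canonical variant key to MRR.
#' @export
oracle_mrr <- function(manifest, denominator = c("all_files", "files_present")) {
  denominator <- match.arg(denominator)
  keys <- sort(unique(unlist(lapply(manifest$files, function(f) f$key))))
  total <- stats::setNames(numeric(length(keys)), keys)
  present <- stats::setNames(integer(length(keys)), keys)
  for (f in manifest$files) {
    usable <- !is.na(f$weight)
    k <- f$key[usable]
    aw <- abs(f$weight[usable])
    if (length(aw) == 0L) next
    ord <- order(aw, decreasing = TRUE)
    position <- integer(length(aw))
    position[ord] <- seq_along(ord)
    rr <- numeric(length(aw))
    for (val in unique(aw)) {
      idx <- which(aw == val)
      rr[idx] <- mean(1 / position[idx])
    }
    for (j in seq_along(k)) {
      total[[k[j]]] <- total[[k[j]]] + rr[j]
      present[[k[j]]] <- present[[k[j]]] + 1L
    }
  }
  if (denominator == "all_files") {
    total / manifest$n_files
  } else {
    out <- total / pmax(present, 1L)
    out[present == 0L] <- 0
    out
  }
}
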