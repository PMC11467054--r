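# In-memory scoring-file builders shared across the suite.

make_records <- function(rsid = NULL, weights, chr = NULL, pos = NULL) {
  n <- length(weights)
  tibble::tibble(
    rsid = if (is.null(rsid)) rep(NA_character_, n) else rsid,
    chr = if (is.null(chr)) rep(NA_character_, n) else as.character(chr),
    pos = if (is.null(pos)) rep(NA_real_, n) else as.numeric(pos),
    effect_allele = rep("A", n),
    other_allele = rep("G", n),
    effect_weight = as.numeric(weights),
    hm_rsid = rep(NA_character_, n),
    hm_chr = rep(NA_character_, n),
    hm_pos = rep(NA_real_, n)
  )
}

make_sf <- function(pgs_id, rsid = NULL, weights = numeric(),
                    chr = NULL, pos = NULL, trait = "test trait") {
  structure(
    list(
      pgs_id = pgs_id,
      trait_label = trait,
      genome_build = "GRCh38",
      metadata = list(pgs_id = pgs_id, genome_build = "GRCh38"),
      records = make_records(rsid, weights, chr, pos),
      n_rejected = 0L,
      source_path = NA_character_
    ),
    class = "pgs_scoring_file"
  )
}

write_scoring_lines <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

minimal_lines <- c(
  "#pgs_id=PGS000001",
  "#genome_build=GRCh38",
  "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
  "rs111\t1\t1000\tA\tG\t0.5",
  "rs222\t2\t2000\tC\tT\t-0.25"
)

write_annotation_lines <- function(lines) {
  p <- tempfile(fileext = ".txt")
  writeLines(lines, p)
  p
}

# Random in-memory scoring file for round-trip properties.
random_sf <- function(i, n = NULL) {
  n <- n %||% sample(1:30, 1)
  use_coord <- runif(n) < 0.4
  rec <- tibble::tibble(
    rsid = ifelse(use_coord, NA_character_, paste0("rs", sample.int(1e7, n))),
    chr = ifelse(use_coord, as.character(sample(1:22, n, TRUE)), NA_character_),
    pos = ifelse(use_coord, sample.int(1e8, n), NA_real_),
    effect_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    other_allele = ifelse(
      runif(n) < 0.1, NA_character_, sample(c("A", "C", "G", "T"), n, TRUE)
    ),
    effect_weight = ifelse(
      runif(n) < 0.15, NA_real_,
      rnorm(n, 0, 0.05) * 10^sample(-5:1, n, TRUE)
    ),
    hm_rsid = NA_character_,
    hm_chr = NA_character_,
    hm_pos = NA_real_
  )
  structure(
    list(
      pgs_id = sprintf("PGS%06d", i),
      trait_label = "round trip",
      genome_build = "GRCh38",
      metadata = list(),
      records = rec,
      n_rejected = 0L,
      source_path = NA_character_
    ),
    class = "pgs_scoring_file"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
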