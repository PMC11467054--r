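test_that("a minimal scoring file parses with metadata and record order", {
  p <- write_scoring_lines(minimal_lines)
  sf <- read_scoring_file(p)
  expect_s3_class(sf, "pgs_scoring_file")
  expect_identical(sf$pgs_id, "PGS000001")
  expect_identical(sf$genome_build, "GRCh38")
  expect_identical(nrow(sf$records), 2L)
  expect_identical(sf$records$rsid, c("rs111", "rs222"))
  expect_identical(sf$records$effect_weight, c(0.5, -0.25))
})

test_that("gzipped files parse identically to plain files", {
  p <- write_scoring_lines(minimal_lines)
  pg <- tempfile(fileext = ".txt.gz")
  con <- gzfile(pg, "wb")
  writeLines(minimal_lines, con)
  close(con)
  expect_identical(read_scoring_file(pg)$records, read_scoring_file(p)$records)
})

test_that("missing tokens NA, empty and dot all parse to missing", {
  p <- write_scoring_lines(c(
    "#pgs_id=PGS000002",
    "rsID\teffect_allele\tother_allele\teffect_weight",
    "rs1\tA\tNA\tNA",
    "rs2\tC\t.\t.",
    "rs3\tG\tT\t",
    "rs4\tT\tA\t1e-7"
  ))
  sf <- read_scoring_file(p)
  expect_identical(sf$records$effect_weight, c(NA, NA, NA, 1e-7))
  expect_identical(sf$records$other_allele, c(NA, NA, "T", "A"))
})

test_that("format errors are raised for degenerate files", {
  no_weight <- write_scoring_lines(c(
    "#pgs_id=PGS000003", "rsID\teffect_allele", "rs1\tA"
  ))
  expect_error(read_scoring_file(no_weight), "effect_weight")

  empty <- write_scoring_lines(c(
    "#pgs_id=PGS000003", "rsID\teffect_allele\teffect_weight"
  ))
  expect_error(read_scoring_file(empty), "empty data section")

  bad_weight <- write_scoring_lines(c(
    "#pgs_id=PGS000003", "rsID\teffect_allele\teffect_weight",
    "rs1\tA\t0.5", "rs2\tC\tnot_a_number"
  ))
  expect_error(read_scoring_file(bad_weight), "row\\(s\\) 2")

  bad_id <- write_scoring_lines(c(
    "#pgs_id=PGS01", "rsID\teffect_allele\teffect_weight", "rs1\tA\t0.5"
  ))
  expect_error(read_scoring_file(bad_id), "pgs_id")
})

test_that("records without locatable identifiers are rejected with a count", {
  p <- write_scoring_lines(c(
    "#pgs_id=PGS000004",
    "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
    "rs1\t1\t100\tA\t0.5",
    "NA\tNA\tNA\tA\t0.2",
    "NA\t2\tNA\tC\t0.1",
    "rs4\t1\t-5\tG\t0.3"
  ))
  expect_warning(sf <- read_scoring_file(p), "3 record\\(s\\) rejected")
  expect_identical(sf$records$rsid, "rs1")
  expect_identical(sf$n_rejected, 3L)
})

test_that("harmonized column dialect and extra columns are handled", {
  p <- write_scoring_lines(c(
    "#pgs_id=PGS000005",
    "hm_rsID\thm_chr\thm_pos\teffect_allele\teffect_weight\tlocus_name",
    "rs9\tchr19\t44908684\tA\t5.82e-7\tAPOE_region"
  ))
  sf <- read_scoring_file(p)
  expect_identical(sf$records$hm_rsid, "rs9")
  expect_identical(sf$records$effect_weight, 5.82e-7)
  expect_identical(sf$records$locus_name, "APOE_region")
})

test_that("write then parse is the identity on record fields", {
  set.seed(101)
  for (i in 1:50) {
    sf <- random_sf(i)
    gz <- i %% 2 == 0
    p <- tempfile(fileext = if (gz) ".txt.gz" else ".txt")
    write_scoring_file(sf, p)
    back <- read_scoring_file(p)
    expect_identical(back$pgs_id, sf$pgs_id)
    expect_identical(back$genome_build, sf$genome_build)
    for (col in c("rsid", "chr", "effect_allele", "other_allele")) {
      expect_identical(back$records[[col]], sf$records[[col]])
    }
    expect_equal(back$records$pos, sf$records$pos)
    expect_identical(back$records$effect_weight, sf$records$effect_weight)
  }
})

test_that("missing cells serialize as NA and survive a round trip", {
  sf <- make_sf("PGS000010", rsid = c("rs1", "rs2"), weights = c(0.5, NA))
  sf$records$other_allele[1] <- NA_character_
  p <- tempfile(fileext = ".txt")
  write_scoring_file(sf, p)
  body <- readLines(p)
  expect_match(body[grepl("^rs1\t", body)], "\tNA\t")
  back <- read_scoring_file(p)
  expect_identical(back$records$other_allele[1], NA_character_)
  expect_identical(back$records$effect_weight[2], NA_real_)
})

test_that("writing an empty scoring file is refused", {
  sf <- make_sf("PGS000011", rsid = character(), weights = numeric())
  expect_error(write_scoring_file(sf, tempfile()), "zero records")
})

test_that("annotation tables load, normalize keys and multi-map", {
  p <- write_annotation_lines(c(
    "variant\tgene\tcategory",
    "rs429358\tAPOE\texonic",
    "RS429358\tTOMM40\tintronic",
    "chr19:44908684\tAPOC1\tupstream",
    "rs7412\tAPOE\texonic",
    "rs7412\tAPOE\texonic"
  ))
  expect_message(ann <- load_annotation_table(p), "1 duplicate")
  expect_identical(nrow(ann), 4L)
  expect_setequal(
    ann$gene[ann$variant_key == "rs429358"], c("APOE", "TOMM40")
  )
  expect_true("19:44908684" %in% ann$variant_key)
})

test_that("annotation table without a gene column is a format error", {
  p <- write_annotation_lines(c("variant\tcategory", "rs1\texonic"))
  expect_error(load_annotation_table(p), "gene symbol")
})
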