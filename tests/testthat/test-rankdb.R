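# One small built database shared by the query tests.
demo_db <- local({
  f1 <- make_sf(
    "PGS000001",
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    weights = c(0.9, 0.5, -0.5, 0.1, NA),
    trait = "Alzheimer's disease"
  )
  f2 <- make_sf(
    "PGS000002",
    rsid = c("rs1", "rs2", "rs6"),
    weights = c(0.8, 0.2, 0.4),
    trait = "Alzheimer's disease"
  )
  ds <- merge_trait_files("Alzheimer's disease", list(f1, f2))
  ranks <- aggregate_mrr(ds)
  ann <- tibble::tibble(
    variant_key = c("rs1", "rs2", "rs2", "rs6"),
    gene = c("APOE", "APOE", "TOMM40", "CLU"),
    category = "exonic"
  )
  genes <- suppressMessages(gene_scores(ranks, ann))
  path <- tempfile(fileext = ".sqlite")
  db <- build_rank_db(
    ds, ranks,
    gene_ranks = genes, summaries = trait_summary(ds), path = path
  )
  list(db = db, ds = ds, ranks = ranks, genes = genes, path = path)
})

test_that("table row counts equal the input list lengths", {
  con <- DBI::dbConnect(RSQLite::SQLite(), demo_db$path)
  on.exit(DBI::dbDisconnect(con))
  n <- function(tbl) {
    DBI::dbGetQuery(con, paste("SELECT COUNT(*) AS n FROM", tbl))$n
  }
  expect_identical(n("traits"), 1L)
  expect_identical(n("scores"), 2L)
  expect_identical(n("variant_ranks"), nrow(demo_db$ranks))
  expect_identical(n("gene_ranks"), nrow(demo_db$genes))
  expect_identical(n("summary"), 1L)
  expect_identical(
    DBI::dbGetQuery(con, "PRAGMA user_version")$user_version, 1L
  )
})

test_that("rebuilding from identical inputs gives identical query results", {
  p2 <- tempfile(fileext = ".sqlite")
  db2 <- build_rank_db(
    demo_db$ds, demo_db$ranks,
    gene_ranks = demo_db$genes,
    summaries = trait_summary(demo_db$ds), path = p2
  )
  expect_identical(
    query_top_variants(demo_db$db, "Alzheimer", 100),
    query_top_variants(db2, "Alzheimer", 100)
  )
  expect_identical(
    query_top_genes(demo_db$db, "Alzheimer", 100),
    query_top_genes(db2, "Alzheimer", 100)
  )
})

test_that("an existing path requires overwrite = TRUE", {
  expect_error(
    build_rank_db(demo_db$ds, demo_db$ranks, path = demo_db$path),
    "already exists"
  )
})

test_that("constraint violations abort the build and leave no file behind", {
  dup <- rbind(demo_db$ranks[1, ], demo_db$ranks[1, ])
  p <- tempfile(fileext = ".sqlite")
  expect_error(
    build_rank_db(demo_db$ds, dup, path = p),
    "build aborted"
  )
  expect_false(file.exists(p))
  expect_false(file.exists(paste0(p, ".build.tmp")))

  bad_mrr <- demo_db$ranks
  bad_mrr$mrr[1] <- 1.5
  expect_error(build_rank_db(demo_db$ds, bad_mrr, path = p), "build aborted")
})

test_that("top-variant queries order by mrr then key and truncate at n", {
  top <- query_top_variants(demo_db$db, "Alzheimer's disease", 2)
  expect_identical(nrow(top), 2L)
  expect_identical(top$variant_key[1], "rs1")  # ranked 1 in both files
  expect_identical(top$mrr[1], 1)
  full <- query_top_variants(demo_db$db, "Alzheimer's disease", 1000)
  expect_identical(nrow(full), nrow(demo_db$ranks))
  expect_true(all(diff(full$mrr) <= 0))
  ties <- split(full$variant_key, full$mrr)
  expect_true(all(vapply(ties, function(k) !is.unsorted(k), logical(1))))
})

test_that("equal-mrr variants break ties lexicographically", {
  # rs2 (0.5, 0.5) and rs3 (0.5, absent) differ; craft an exact tie instead
  f <- make_sf("PGS000009", rsid = c("rsb", "rsa"), weights = c(0.5, -0.5))
  ds <- merge_trait_files("tie trait", list(f))
  p <- tempfile(fileext = ".sqlite")
  db <- build_rank_db(ds, aggregate_mrr(ds), path = p)
  top <- query_top_variants(db, "tie trait", 2)
  expect_identical(top$variant_key, c("rsa", "rsb"))
})

test_that("trait matching is case-insensitive with substring fallback", {
  expect_identical(
    query_top_variants(demo_db$db, "alzheimer's disease", 1),
    query_top_variants(demo_db$db, "Alzheimer", 1)
  )
  expect_error(query_top_variants(demo_db$db, "XYZ", 1), "available traits")
})

test_that("top-gene queries return each gene once, ordered", {
  g <- query_top_genes(demo_db$db, "Alzheimer", 10)
  expect_lte(nrow(g), 10L)
  expect_identical(anyDuplicated(g$gene), 0L)
  expect_identical(g$gene[1], "APOE")  # carries rs1, mrr 1
  expect_true(all(diff(g$score) <= 0))
})

test_that("n must be at least 1 and queries are repeatable", {
  expect_error(query_top_variants(demo_db$db, "Alzheimer", 0))
  expect_identical(
    query_top_genes(demo_db$db, "Alzheimer", 3),
    query_top_genes(demo_db$db, "Alzheimer", 3)
  )
})

test_that("the integrity check passes on a built database", {
  expect_identical(db_integrity_check(demo_db$db), character(0))
})

test_that("the integrity check reports a dangling trait reference", {
  p <- tempfile(fileext = ".sqlite")
  file.copy(demo_db$path, p)
  con <- DBI::dbConnect(RSQLite::SQLite(), p)
  DBI::dbExecute(con, "DELETE FROM traits")
  DBI::dbDisconnect(con)
  bad <- db_integrity_check(rank_db(p))
  expect_true(any(grepl("missing trait", bad)))
})

test_that("summary rows round-trip through the database", {
  s <- query_trait_summary(demo_db$db)
  ref <- trait_summary(demo_db$ds)
  expect_identical(s$trait, ref$trait)
  expect_equal(s$mean, ref$mean)
  expect_equal(s$sd, ref$sd)
  expect_identical(s$n_files, ref$n_files)
})
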