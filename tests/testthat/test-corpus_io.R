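# Reading, validation and filtering of assay and bioactivity tables.

test_that("assay table reads identity with provenance and rejects bad schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_tiny_assay_tsv(path, 3L)
  corpus <- read_assay_table(path)
  expect_s3_class(corpus, "assay_corpus")
  expect_equal(nrow(corpus), 3L)
  expect_equal(corpus$assay_id, df$assay_id)
  expect_equal(corpus$description, df$description)
  expect_match(provenance(corpus)[1], basename(path), fixed = TRUE)

  # missing description column -> schema error naming it
  df2 <- df[, setdiff(names(df), "description")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_assay_table(path2), "description")

  # duplicated assay_id -> integrity error listing the offender
  df3 <- df; df3$assay_id <- c("A1", "A1", "A3")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df3, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_assay_table(path3), "A1")
})

test_that("assay filter applies strict length and type rules with counts", {
  long <- paste(rep("x", 501), collapse = "")
  exact <- paste(rep("y", 500), collapse = "")
  corpus <- tiny_corpus(c(long, exact, "short binding assay", "admet panel"))
  corpus$assay_type <- c("B", "B", "B", "A")
  out <- filter_assay_corpus(corpus)
  expect_equal(out$description, c(exact, "short binding assay"))
  expect_match(paste(provenance(out), collapse = " "), "removed 1 records",
               all = FALSE)
  # idempotent
  out2 <- filter_assay_corpus(out)
  expect_equal(plain_df(out2), plain_df(out))
})

test_that("bioactivity reads collect rejects and filters apply in order", {
  df <- data.frame(
    compound_id = c("C1", "C2", "C3", "C4"),
    smiles = "c1ccccc1",
    target_accession = c("P1", "P1", "P1", "P1"),
    pchembl = c("6.5", "NA", "7.1", "5.0"),
    assay_id = paste0("A", 1:4), standard_type = "Ki",
    quality_flag = c("high", "high", "Low quality", "high"),
    censored = c("FALSE", "FALSE", "FALSE", "TRUE"),
    mw = c(350, 350, 350, 1001))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab <- read_bioactivity_table(path)
  expect_equal(nrow(tab), 3L)  # NA pchembl on uncensored row diverted
  expect_equal(nrow(rejects(tab)), 1L)
  expect_match(rejects(tab)$reject_reason, "pchembl")
  expect_equal(tab$pchembl[1], 6.5)

  filtered <- suppressWarnings(filter_bioactivity(
    tab, min_unique_compounds_per_target = 0L))
  # low-quality and censored and heavy rows all removed
  expect_equal(filtered$compound_id, "C1")
  # disabled rule retains censored points
  kept <- suppressWarnings(filter_bioactivity(
    tab, min_unique_compounds_per_target = 0L, drop_censored = FALSE,
    drop_low_quality = FALSE, max_mw = 2000))
  expect_equal(nrow(kept), 3L)
})

test_that("a document exclusion list removes the matching data points", {
  df <- data.frame(compound_id = paste0("c", 1:4), target_accession = "P1",
                   pchembl = 6, document_id = c("doc1", "doc2", "doc1", NA))
  tab <- tiny_bioactivity(df)
  out <- suppressWarnings(filter_bioactivity(
    tab, min_unique_compounds_per_target = 0L, exclude_documents = "doc1"))
  expect_equal(out$compound_id, c("c2", "c4"))
  expect_match(paste(provenance(out), collapse = " "), "excluded documents")
})

test_that("compound-count rule is strict, target-level, and applied last", {
  # target P1: 101 compounds (one removed by mw -> exactly 100 left);
  # target P2: 101 compounds, all clean
  df <- rbind(
    data.frame(compound_id = paste0("c", 1:101), target_accession = "P1",
               pchembl = 6, mw = c(1500, rep(300, 100))),
    data.frame(compound_id = paste0("d", 1:101), target_accession = "P2",
               pchembl = 6, mw = 300))
  tab <- tiny_bioactivity(df)
  out <- filter_bioactivity(tab)
  # P1 fell to exactly 100 unique compounds after the mw filter -> dropped
  expect_false("P1" %in% out$target_accession)
  expect_equal(sum(out$target_accession == "P2"), 101L)
})

test_that("row-level filter composition order does not change the result", {
  df <- data.frame(compound_id = paste0("c", 1:20),
                   target_accession = "P1", pchembl = 6,
                   mw = sample(c(300, 1200), 20, replace = TRUE),
                   censored = sample(c(TRUE, FALSE), 20, replace = TRUE),
                   quality_flag = sample(c("high", "low"), 20, replace = TRUE))
  tab <- tiny_bioactivity(df)
  a <- suppressWarnings(filter_bioactivity(tab, min_unique_compounds_per_target = 0L))
  # reverse order: censored first, then quality, then mw via successive calls
  b <- suppressWarnings(filter_bioactivity(
    tab, min_unique_compounds_per_target = 0L, drop_low_quality = FALSE,
    max_mw = Inf))
  b <- suppressWarnings(filter_bioactivity(
    b, min_unique_compounds_per_target = 0L, drop_censored = FALSE,
    max_mw = Inf))
  b <- suppressWarnings(filter_bioactivity(
    b, min_unique_compounds_per_target = 0L, drop_censored = FALSE,
    drop_low_quality = FALSE))
  expect_equal(sort(paste(a$compound_id)), sort(paste(b$compound_id)))
})

test_that("corpus write -> read round-trips field-for-field", {
  syn <- generate_assay_corpus(default_archetypes(3), 5L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assay_corpus(syn$corpus, path)
  back <- read_assay_table(path)
  expect_equal(plain_df(back), plain_df(syn$corpus))
})

test_that("pChEMBL conversion matches its definition", {
  expect_equal(compute_pchembl(1e-6), 6.0)
  expect_equal(compute_pchembl(1), 0.0)
  expect_equal(compute_pchembl(3.16e-8), 7.5, tolerance = 0.01)
  expect_error(compute_pchembl(0), "positive")
  expect_error(compute_pchembl(-1), "positive")
})
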