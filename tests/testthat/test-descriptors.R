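# Metadata one-hot fingerprints, bag-of-words fingerprints, and the
# embedder contract.

test_that("metadata property selection honors coverage and category caps", {
  corpus <- tiny_corpus(paste("assay description", 1:50))
  corpus$bao_format <- paste0("BAO_", seq_len(50))      # 50 categories
  corpus$curated_by[1] <- NA                            # one missing value
  props <- select_metadata_properties(corpus, max_categories = 40L)
  expect_false("bao_format" %in% props)   # 41+ categories excluded
  expect_false("curated_by" %in% props)   # < 100% coverage excluded
  expect_true(all(c("assay_type", "standard_type") %in% props))
  # 41 categories is over the cap, 40 is not
  corpus$bao_format <- c(paste0("B", 1:41), paste0("B", 1:9))
  expect_false("bao_format" %in% select_metadata_properties(corpus))
  corpus$bao_format <- rep(paste0("B", 1:40), length.out = 50)
  expect_true("bao_format" %in% select_metadata_properties(corpus))
})

test_that("metadata fingerprint is one-hot per property block", {
  corpus <- tiny_corpus(paste("desc", 1:6))
  corpus$assay_type <- c("B", "F", "B", "F", "B", "B")          # 2 categories
  corpus$standard_type <- c("Ki", "IC50", "EC50", "Ki", "Ki", "EC50")  # 3
  fp <- build_metadata_fingerprint(corpus, c("standard_type", "assay_type"))
  expect_equal(ncol(fp), 5L)
  expect_equal(descriptor_kind(fp), "metadata_fp")
  st_block <- unclass(fp)[, startsWith(colnames(fp), "standard_type=")]
  at_block <- unclass(fp)[, startsWith(colnames(fp), "assay_type=")]
  expect_true(all(rowSums(st_block) == 1))
  expect_true(all(rowSums(at_block) == 1))

  # unseen category at apply time -> all-zero block with warning
  new_corpus <- tiny_corpus("desc x")
  new_corpus$assay_type <- "B"; new_corpus$standard_type <- "Kd"
  expect_warning(
    fp2 <- build_metadata_fingerprint(new_corpus,
                                      c("standard_type", "assay_type"),
                                      levels = attr(fp, "levels")),
    "unseen")
  expect_equal(sum(unclass(fp2)[1, startsWith(colnames(fp2), "standard_type=")]), 0)
  expect_equal(colnames(fp2), colnames(fp))
})

test_that("bag-of-words fingerprint is binary, capped, and reproducible", {
  corpus <- tiny_corpus(c("camp camp forskolin stimulation",
                          "radioligand displacement membranes",
                          "camp kinase substrate"))
  res <- build_bow_fingerprint(corpus)
  m <- res$matrix
  expect_equal(descriptor_kind(m), "bow_fp")
  # cap not binding: columns = distinct tokens
  expect_true(ncol(m) < 1024L)
  # presence not count: "camp" appears twice in doc 1 but bit is 1
  expect_equal(unname(unclass(m)[1, "camp"]), 1)
  expect_true(all(unclass(m) %in% c(0, 1)))
  # bit-exact rebuild from the vocabulary spec
  res2 <- build_bow_fingerprint(corpus, vocabulary = res$vocabulary)
  expect_identical(unclass(res2$matrix), unclass(m))
  # cap binding: top-df terms with lexicographic ties
  res3 <- build_bow_fingerprint(corpus, max_bits = 2L)
  expect_equal(ncol(res3$matrix), 2L)
  expect_true("camp" %in% colnames(res3$matrix))  # highest document frequency
})

test_that("descriptor builders are order-equivariant", {
  syn <- generate_assay_corpus(default_archetypes(3), 10L, seed = 5L)
  corpus <- syn$corpus
  perm <- sample(nrow(corpus))
  corpus_p <- assaycontext:::new_assay_corpus(
    as.data.frame(corpus)[perm, , drop = FALSE])
  bow <- build_bow_fingerprint(corpus)$matrix
  bow_p <- build_bow_fingerprint(corpus_p)$matrix
  expect_equal(unclass(bow_p), unclass(bow)[perm, , drop = FALSE],
               ignore_attr = TRUE)
  emb <- embed_descriptions(corpus, hash_projection_embedder(16, 9))
  emb_p <- embed_descriptions(corpus_p, hash_projection_embedder(16, 9))
  expect_equal(unclass(emb_p), unclass(emb)[perm, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("hash-projection embedder is deterministic, unit-norm, and broadcasts", {
  emb <- hash_projection_embedder(32, 7)
  a <- emb$embed(c("camp forskolin assay", "camp forskolin assay"))
  expect_identical(a[1, ], a[2, ])
  expect_equal(sqrt(sum(a[1, ]^2)), 1, tolerance = 1e-12)
  # identical descriptions -> identical rows through the corpus interface
  corpus <- tiny_corpus(c("same text here", "same text here", "different one"))
  m <- embed_descriptions(corpus, emb)
  expect_identical(unclass(m)[1, ], unclass(m)[2, ])
  expect_false(all(unclass(m)[1, ] == unclass(m)[3, ]))
  expect_equal(ncol(m), 32L)
  # dimension contract mirrors the reference embedders
  expect_equal(hash_projection_embedder(768, 1)$dimension, 768L)
  expect_equal(hash_projection_embedder(1536, 1)$dimension, 1536L)
})

test_that("hash projection approximately preserves hashed-count cosines", {
  emb <- hash_projection_embedder(512, 11)
  vocab <- c("camp", "forskolin", "kinase", "displacement", "membranes",
             "calcium", "flipr", "uptake", "radioligand", "substrate",
             "buffer", "plate", "signal", "response", "incubation")
  set.seed(23)
  diffs <- replicate(100, {
    t1 <- paste(sample(vocab, 8, replace = TRUE), collapse = " ")
    t2 <- paste(sample(vocab, 8, replace = TRUE), collapse = " ")
    h1 <- assaycontext:::.hashed_counts(t1)
    h2 <- assaycontext:::.hashed_counts(t2)
    true_cos <- sum(h1 * h2) / sqrt(sum(h1^2) * sum(h2^2))
    e <- emb$embed(c(t1, t2))
    emb_cos <- sum(e[1, ] * e[2, ])
    abs(emb_cos - true_cos)
  })
  expect_lt(max(diffs), 0.15)
})

test_that("descriptor matrices round-trip through TSV + JSON sidecar", {
  corpus <- tiny_corpus(c("camp forskolin", "radioligand membranes"))
  res <- build_bow_fingerprint(corpus)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_matrix(res$matrix, path, corpus)
  back <- read_descriptor_matrix(path)
  expect_equal(descriptor_kind(back), "bow_fp")
  expect_equal(unclass(back), unclass(res$matrix), ignore_attr = TRUE)
})

test_that("overlong descriptions are rejected by the embedder contract", {
  corpus <- tiny_corpus(paste(rep("x", 501), collapse = ""))
  expect_error(embed_descriptions(corpus, hash_projection_embedder(16, 1)),
               "max_input_chars")
})
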