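# Reduction, density clustering, c-TF-IDF, topic words, outlier
# reassignment, and the assembled topic pipeline.

test_that("reduction yields the requested dimension deterministically", {
  set.seed(4)
  x <- matrix(rnorm(100 * 16), 100)
  cfg <- cluster_config(seed = 1L)
  r1 <- reduce_embeddings(x, cfg)
  expect_equal(dim(r1), c(100L, 5L))
  expect_identical(r1, reduce_embeddings(x, cfg))
  expect_error(reduce_embeddings(x[1:10, ], cfg), "n_neighbors")
})

test_that("reduction keeps well-separated archetype blobs separated", {
  set.seed(8)
  blob <- rbind(matrix(rnorm(60 * 16, 0), ncol = 16),
                matrix(rnorm(60 * 16, 4), ncol = 16))
  red <- reduce_embeddings(blob, cluster_config())
  d <- as.matrix(dist(red))
  intra <- mean(d[1:60, 1:60][upper.tri(d[1:60, 1:60])])
  inter <- mean(d[1:60, 61:120])
  expect_gt(inter, intra)
})

test_that("semisupervised reduction pulls labeled groups together", {
  set.seed(9)
  x <- matrix(rnorm(80 * 12), 80)          # no unsupervised structure
  lab <- rep(c("B", "F"), each = 40)
  cfg_sup <- cluster_config(seed = 1L, supervision_labels = lab)
  red <- reduce_embeddings(x, cfg_sup)
  d <- as.matrix(dist(red))
  intra <- mean(d[1:40, 1:40][upper.tri(d[1:40, 1:40])])
  inter <- mean(d[1:40, 41:80])
  expect_gt(inter, intra)
})

test_that("density clustering recovers blobs and respects the size contract", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(200 * 5, 0), ncol = 5),
                 matrix(rnorm(200 * 5, 8), ncol = 5))
  lab <- cluster_reduced(blobs, 16L)
  expect_equal(length(unique(lab[lab != -1L])), 2L)
  expect_gte(mean(lab != -1L), 0.95)
  sizes <- table(lab[lab != -1L])
  expect_true(all(sizes >= 16L))
  # labels relabeled 0..K-1 by descending size
  expect_equal(sort(unique(lab[lab != -1L])), c(0L, 1L))
})

test_that("uniform noise at large min size is labeled as outliers", {
  set.seed(6)
  noise <- matrix(runif(200 * 5), ncol = 5)
  expect_warning(lab <- cluster_reduced(noise, 128L), "outliers")
  expect_gte(mean(lab == -1L), 0.95)
})

test_that("c-TF-IDF matches the hand-computed two-cluster corpus", {
  docs <- list(c("a", "a", "b"), c("b", "c"))
  labels <- c(0L, 1L)
  model <- fit_ctfidf(docs, labels)
  expect_equal(model$mean_tokens_per_cluster, 2.5)
  expect_equal(model$weights["0", "a"], 2 * log(1 + 2.5 / 2),
               tolerance = 1e-10)
  expect_equal(model$weights["1", "c"], 1 * log(1 + 2.5 / 1),
               tolerance = 1e-10)
  # token absent from a cluster has weight exactly 0
  expect_identical(model$weights["0", "c"], 0)
  expect_identical(model$weights["1", "a"], 0)
})

test_that("single-cluster c-TF-IDF is increasing in term frequency", {
  docs <- list(c("a", "a", "a", "b", "c"))
  m <- fit_ctfidf(docs, 0L)
  expect_gt(m$weights["0", "a"], m$weights["0", "b"])
})

test_that("c-TF-IDF equals the brute-force oracle on random corpora", {
  set.seed(12)
  for (i in 1:30) {
    rc <- random_token_corpus(sample(3:10, 1), sample(2:4, 1))
    if (all(rc$labels == -1L)) next
    got <- fit_ctfidf(rc$documents, rc$labels)
    want <- oracle_ctfidf(rc$documents, rc$labels)
    expect_equal(got$weights[rownames(want), colnames(want), drop = FALSE],
                 want, tolerance = 1e-12)
  }
})

test_that("topic words rank by weight with lexicographic ties", {
  docs <- list(c("a", "a", "b"), c("b", "c"))
  model <- fit_ctfidf(docs, c(0L, 1L))
  tw <- topic_words(model, k = 1L)
  expect_equal(tw[["0"]], "a")
  expect_equal(tw[["1"]], "c")
  # k larger than the cluster vocabulary -> full ranked list
  expect_equal(topic_words(model, k = 50L)[["0"]], c("a", "b"))
  # exact tie -> lexicographic order
  m2 <- fit_ctfidf(list(c("z", "d")), 0L)
  expect_equal(topic_words(m2, k = 2L)[["0"]], c("d", "z"))
})

test_that("outlier reassignment follows c-TF-IDF cosine and keeps labels", {
  docs <- list(c("a", "a", "b"), c("b", "c"), c("a", "b"), c("qq"))
  labels <- c(0L, 1L, -1L, -1L)
  model <- fit_ctfidf(docs, labels)
  out <- suppressMessages(reassign_outliers(model, docs, labels))
  expect_false(any(out == -1L))
  expect_equal(out[1:2], labels[1:2])   # non-outlier labels untouched
  # brute-force cosine: count vector (a=1, b=1) is closer to cluster 0
  w <- model$weights
  cos0 <- sum(w["0", c("a", "b")]) / (sqrt(sum(w["0", ]^2)) * sqrt(2))
  cos1 <- sum(w["1", c("a", "b")]) / (sqrt(sum(w["1", ]^2)) * sqrt(2))
  expect_equal(out[3], as.integer(names(which.max(c(`0` = cos0, `1` = cos1)))))
  # zero-overlap outlier went to the largest cluster (cluster 0 has 1 doc,
  # cluster 1 has 1 doc: tie resolved to the first = lower id)
  expect_equal(out[4], 0L)
  # outlier equal to a member of cluster 1 joins cluster 1
  docs2 <- list(c("a", "a", "b"), c("b", "c"), c("b", "c"))
  out2 <- reassign_outliers(model, docs2, c(0L, 1L, -1L))
  expect_equal(out2[3], 1L)
  # no outliers -> identity
  expect_identical(reassign_outliers(model, docs[1:2], c(0L, 1L)), c(0L, 1L))
})

test_that("topic pipeline returns one deterministic model per seed", {
  syn <- generate_assay_corpus(default_archetypes(3), 40L, seed = 21L)
  emb <- embed_descriptions(syn$corpus, hash_projection_embedder(64, 21))
  cfg <- cluster_config(min_cluster_size = 8L, seed = 100L)
  models <- fit_topic_model(syn$corpus, emb, cfg, n_repeats = 3L)
  expect_length(models, 3L)
  expect_equal(vapply(models, `[[`, integer(1), "seed"), c(100L, 101L, 102L))
  # identical inputs -> identical pipeline output
  models2 <- fit_topic_model(syn$corpus, emb, cfg, n_repeats = 3L)
  expect_identical(models[[1]]$labels_record, models2[[1]]$labels_record)
  expect_identical(models[[1]]$ctfidf$weights, models2[[1]]$ctfidf$weights)
  # records inherit the label of their unique description
  desc <- trimws(syn$corpus$description)
  u <- match(desc, models[[1]]$unique_descriptions)
  expect_identical(models[[1]]$labels_record, models[[1]]$labels_unique[u])
  # no -1 after outlier reduction and contiguous labels
  for (m in models) {
    expect_false(any(m$labels_unique == -1L))
    expect_equal(sort(unique(m$labels_unique)),
                 seq(0L, max(m$labels_unique)))
  }
})

test_that("a corpus with one unique description cannot be clustered", {
  corpus <- tiny_corpus(rep("identical text", 30))
  emb <- embed_descriptions(corpus, hash_projection_embedder(16, 1))
  expect_error(fit_topic_model(corpus, emb), "single unique description")
})

test_that("synthetic archetype corpus yields at least one cluster per archetype", {
  syn <- generate_assay_corpus(default_archetypes(5), 60L, seed = 31L)
  emb <- embed_descriptions(syn$corpus, hash_projection_embedder(64, 31))
  models <- fit_topic_model(syn$corpus, emb,
                            cluster_config(min_cluster_size = 16L,
                                           seed = 31L), n_repeats = 1L)
  k <- length(unique(models[[1]]$labels_unique))
  expect_gte(k, 5L)
})

test_that("cluster assignment and topic words serialize to TSV/JSON", {
  syn <- generate_assay_corpus(default_archetypes(3), 40L, seed = 41L)
  emb <- embed_descriptions(syn$corpus, hash_projection_embedder(64, 41))
  m <- fit_topic_model(syn$corpus, emb,
                       cluster_config(min_cluster_size = 8L, seed = 41L),
                       n_repeats = 1L)[[1]]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_cluster_assignment(m, syn$corpus, tsv)
  write_topic_words(m, jsn)
  asg <- read.delim(tsv)
  expect_equal(nrow(asg), nrow(syn$corpus))
  expect_identical(asg$cluster, m$labels_record)
  expect_named(jsonlite::read_json(jsn))
})
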