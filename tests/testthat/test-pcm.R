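# Featurization, filtering, splitting, boosting, and evaluation for the
# PCM models.

test_that("median aggregation follows the stated conventions", {
  df <- data.frame(compound_id = "C1", smiles = "c1ccccc1",
                   target_accession = "P1", pchembl = c(6, 7, 8),
                   assay_id = c("A1", "A2", "A3"))
  ds <- aggregate_measurements(tiny_bioactivity(df), "control")
  expect_equal(ds$pchembl, 7)
  df2 <- df[1:2, ]; df2$pchembl <- c(6, 7)
  expect_equal(aggregate_measurements(tiny_bioactivity(df2), "control")$pchembl,
               6.5)
  # cluster mode groups by context: values {6, 6} in A and {8} in B
  ctx <- c(A1 = "A", A2 = "A", A3 = "B")
  df3 <- df; df3$pchembl <- c(6, 6, 8)
  ds3 <- aggregate_measurements(tiny_bioactivity(df3), "cluster", ctx)
  expect_equal(nrow(ds3), 2L)
  expect_equal(sort(ds3$pchembl), c(6, 8))
  # unresolvable assay ids are dropped and counted
  ds4 <- aggregate_measurements(tiny_bioactivity(df3), "cluster",
                                ctx[c("A1", "A2")])
  expect_equal(attr(ds4, "n_dropped"), 1L)
})

test_that("molecule fingerprints are 2048-bit, deterministic, standardized", {
  fp <- featurize_molecules(c("c1ccccc1", "c1ccccc1", "CCCCCC"))
  expect_equal(ncol(fp), 2048L)
  expect_identical(fp[1, ], fp[2, ])
  expect_false(all(fp[1, ] == fp[3, ]))      # benzene vs hexane differ
  expect_true(all(fp[!is.na(fp)] %in% c(0, 1)))
  # salt stripping: counter-ion dropped before fingerprinting
  fp2 <- featurize_molecules(c("CCO", "CCO.Cl"))
  expect_identical(fp2[1, ], fp2[2, ])
  # unparsable SMILES -> NA row plus errors attribute
  fp3 <- featurize_molecules(c("c1ccccc1", "not_a_smiles("))
  expect_true(all(is.na(fp3[2, ])))
  expect_equal(attr(fp3, "errors"), "not_a_smiles(")
})

test_that("scaffold keys collapse side chains and split ring systems", {
  keys <- murcko_scaffolds(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1",
                             "c1ccc(-c2ccccc2)cc1", "CCCCCC"))
  expect_equal(keys[1], keys[2])   # toluene shares the benzene scaffold
  expect_equal(keys[1], keys[3])
  expect_false(keys[4] == keys[1]) # biphenyl is a different scaffold
  expect_equal(keys[5], "acyclic")
})

test_that("protein z-scale descriptors follow the published table and gap rule", {
  aln <- Biostrings::AAStringSet(c(P1 = "A-C", P2 = "AAC"))
  v <- featurize_protein(aln, "P1")
  expect_length(v, 9L)
  expect_equal(unname(v[1:3]), c(0.07, -1.73, 0.09))  # alanine triple
  expect_equal(unname(v[4:6]), c(0, 0, 0))            # gap position
  expect_equal(unname(v[7:9]), unname(zscale_table()["C", ]))
  expect_warning(featurize_protein(Biostrings::AAStringSet(c(PX = "AXA")), "PX"),
                 "unknown residue")
  expect_error(featurize_protein(aln, "P9"), "not in alignment")
  m <- featurize_proteins(aln, c("P2", "P1"))
  expect_equal(dim(m), c(2L, 9L))
  expect_equal(m["P1", ], v)
})

test_that("feature filters drop low variance then later correlated columns", {
  set.seed(30)
  x <- matrix(rnorm(200 * 4), 200,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  x <- cbind(x, constant = 1, dup_a = x[, "a"])
  # planted correlated pair (r about 0.9): later column must lose
  x <- cbind(x, corr_a = 0.9 * x[, "a"] + sqrt(1 - 0.81) * rnorm(200))
  mask <- apply_feature_filters(x)
  expect_false(mask["constant"])
  expect_true(mask["a"]); expect_false(mask["dup_a"])
  expect_false(mask["corr_a"])
  expect_true(all(mask[c("b", "c", "d")]))
  # mask depends on the training rows only
  expect_identical(apply_feature_filters(x), mask)
})

test_that("random and scaffold splits meet their contracts deterministically", {
  smiles <- assaycontext:::.packaged_smiles()
  set.seed(31)
  ds <- data.frame(compound_id = smiles$compound_id[1:300],
                   smiles = smiles$smiles[1:300],
                   target_accession = "P1", pchembl = rnorm(300))
  sp <- split_dataset(ds, "random", 0.1, seed = 3L)
  expect_length(sp$test_idx, 30L)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(300))
  expect_identical(split_dataset(ds, "random", 0.1, seed = 3L)$test_idx,
                   sp$test_idx)
  sc <- split_dataset(ds, "scaffold", 0.1, seed = 3L)
  expect_gt(length(unique(sc$scaffolds)), 20L)
  expect_length(intersect(sc$scaffolds[sc$train_idx],
                          sc$scaffolds[sc$test_idx]), 0L)
  frac <- length(sc$test_idx) / 300
  expect_lt(abs(frac - 0.1), 0.05)
  expect_identical(split_dataset(ds, "scaffold", 0.1, seed = 3L)$test_idx,
                   sc$test_idx)
  # single scaffold -> impossible
  ds1 <- ds[1:20, ]; ds1$smiles <- "c1ccccc1"
  expect_error(split_dataset(ds1, "scaffold"), "single scaffold")
})

test_that("single-task boosting fits recoverable signal deterministically", {
  set.seed(32)
  x <- matrix(rbinom(400 * 10, 1, 0.5), 400,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- x[, 3] * 2
  spec <- boosting_spec(max_trees = 200, min_points_per_leaf = 20)
  m <- train_single_task(x, y, spec, seed = 5L)
  expect_lte(m$n_trees, 1000L)
  p <- predict(m, x)
  r2 <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.95)
  m2 <- train_single_task(x, y, spec, seed = 5L)
  expect_identical(predict(m2, x), p)
  expect_error(train_single_task(x, c(y[-1], NA), spec), "finite")
})

test_that("multitask with one full task reduces exactly to single-task", {
  set.seed(33)
  x <- matrix(rnorm(300 * 8), 300, dimnames = list(NULL, paste0("f", 1:8)))
  y <- x[, 1] + rnorm(300, sd = 0.1)
  spec <- boosting_spec(max_trees = 100, min_points_per_leaf = 20)
  single <- train_single_task(x, y, spec, seed = 9L)
  multi <- train_multitask(x, matrix(y, ncol = 1), spec = spec, seed = 9L)
  expect_identical(as.vector(predict_multitask(multi, x)),
                   as.vector(predict(single, x)))
})

test_that("masked entries contribute nothing to the multitask fit", {
  set.seed(34)
  x <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  Y <- cbind(t1 = x[, 1] + rnorm(200, sd = 0.1),
             t2 = x[, 2] + rnorm(200, sd = 0.1))
  mask <- matrix(rbinom(400, 1, 0.6), 200)
  spec <- boosting_spec(max_trees = 60, min_points_per_leaf = 15)
  m1 <- train_multitask(x, Y, mask, spec, seed = 4L)
  # perturb the target at masked entries only: the fit must not move
  Y2 <- Y
  Y2[mask == 0] <- Y2[mask == 0] + 100
  m2 <- train_multitask(x, Y2, mask, spec, seed = 4L)
  expect_identical(predict_multitask(m1, x), predict_multitask(m2, x))
  # tasks with disjoint row support train without error
  Y3 <- matrix(NA_real_, 150, 3)
  Y3[1:50, 1] <- rnorm(50); Y3[51:100, 2] <- rnorm(50)
  Y3[101:150, 3] <- rnorm(50)
  x3 <- matrix(rnorm(150 * 5), 150, dimnames = list(NULL, paste0("g", 1:5)))
  m3 <- train_multitask(x3, Y3, spec = boosting_spec(max_trees = 20,
                                                     min_points_per_leaf = 5),
                        seed = 1L)
  expect_equal(dim(predict_multitask(m3, x3)), c(150L, 3L))
})

test_that("masked R-squared reduces to plain R-squared under a full mask", {
  y <- c(1, 2, 3, 4); p <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(masked_r2(y, y), 1)
  expect_equal(masked_r2(y, rep(mean(y), 4)), 0)
  expect_equal(masked_r2(y, p), 1 - sum((y - p)^2) / sum((y - mean(y))^2))
  Y <- matrix(c(1, 2, NA, 4), 2); P <- matrix(c(1, 2, 0, 4), 2)
  expect_equal(masked_r2(Y, P, !is.na(Y)), 1)
  expect_error(masked_r2(c(1, 1), c(1, 1)), "zero variance")
})

test_that("evaluation reports R2, RMSE and tie-corrected Kendall's Tau", {
  set.seed(35)
  x <- matrix(rnorm(300 * 5), 300, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, 1]
  m <- train_single_task(x, y, boosting_spec(max_trees = 50,
                                             min_points_per_leaf = 20),
                         seed = 2L)
  rep <- evaluate_model(m, x, y)
  expect_named(rep, c("task", "r2", "rmse", "kendall_tau", "n"))
  # perfect and reversed predictions through the metric helper
  perfect <- assaycontext:::.single_metrics(1:10, 1:10)
  expect_equal(unname(perfect), c(1, 0, 1))
  reversed <- assaycontext:::.single_metrics(1:10, 10:1)
  expect_equal(unname(reversed["kendall_tau"]), -1)
  # task-size weighting: (0.5 * 10 + 1.0 * 30) / 40 = 0.875
  expect_equal((0.5 * 10 + 1 * 30) / 40, 0.875)
})

test_that("multitask evaluation weights tasks by test-set size", {
  set.seed(36)
  x <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("f", 1:5)))
  Y <- cbind(a = x[, 1] + rnorm(200, sd = 0.2),
             b = x[, 2] + rnorm(200, sd = 0.2))
  mask <- cbind(rep(1, 200), rep(c(1, 0), each = 100))
  m <- train_multitask(x, Y, mask, boosting_spec(max_trees = 40,
                                                 min_points_per_leaf = 15),
                       seed = 3L)
  ev <- evaluate_model(m, x, Y, mask)
  expect_true("weighted" %in% ev$task)
  per <- ev[ev$task != "weighted", ]
  w <- per$n / sum(per$n)
  expect_equal(ev$r2[ev$task == "weighted"], sum(w * per$r2))
})

test_that("feature importance ranks the generating feature first", {
  set.seed(37)
  x <- matrix(rnorm(300 * 6), 300, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 3 * x[, 4]
  m <- train_single_task(x, y, boosting_spec(max_trees = 60,
                                             min_points_per_leaf = 20),
                         seed = 6L)
  imp <- feature_importance(m, blocks = rep(c("molecule", "protein"), 3),
                            top_k = 5L)
  expect_equal(imp$feature[1], "f4")
  props <- attr(imp, "block_proportions")
  expect_equal(sum(props), 1)
})

test_that("assay-aware model beats control on offset-dominated synthetic data", {
  syn <- generate_bioactivity(6, 40, default_archetypes(4),
                              replicate_rate = 2, offset_sd = 0.8,
                              noise_sd = 0.2, seed = 55L)
  spec <- boosting_spec(max_trees = 150, min_points_per_leaf = 20)
  ctrl <- run_pcm_experiment(syn$table, syn$corpus$corpus, syn$alignment,
                             mode = "control", seed = 55L, spec = spec)
  emb <- run_pcm_experiment(syn$table, syn$corpus$corpus, syn$alignment,
                            mode = "embedding", seed = 55L, spec = spec)
  expect_gt(emb$metrics$r2, ctrl$metrics$r2)
  # the filter mask is computed on training rows only
  expect_equal(length(ctrl$mask),
               ncol(build_feature_matrix(
                 aggregate_measurements(syn$table, "control"),
                 syn$alignment)$x))
})
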