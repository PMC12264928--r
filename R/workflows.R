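# End-to-end PCM experiment: aggregation under the chosen assay-context
# mode, feature assembly, train-only filtering, splitting, boosting, and
# test-set evaluation. This is the composition the `train` subcommand and
# the package's own experiments run.

#' Run one assay-aware PCM experiment
#'
#' Modes mirror the ways of injecting assay context into a PCM model:
#' `control` aggregates each compound-target pair over all its measurements
#' and uses molecule + protein features only; `embedding`, `bow` and
#' `metadata` aggregate per (compound, target, assay description) and append
#' the corresponding assay-descriptor block; `multitask` aggregates per
#' (compound, target, assay cluster) and trains one output per cluster with
#' masked loss, the clusters coming from a topic model fitted on the corpus.
#'
#' @param table A `bioactivity_table`.
#' @param corpus The matching `assay_corpus`.
#' @param alignment FASTA path or `AAStringSet` with all target accessions.
#' @param mode One of `"control"`, `"embedding"`, `"bow"`, `"metadata"`,
#'   `"multitask"`.
#' @param split_method `"random"` or `"scaffold"`.
#' @param test_fraction Test fraction (default 0.1).
#' @param seed Integer seed (split, holdout, subsampling, embedder).
#' @param embedding_dim Hash-projection embedder dimension (default 64).
#' @param spec A [boosting_spec()].
#' @param min_cluster_size Minimum cluster size for the multitask topic
#'   model (default 16).
#' @return List: `metrics` (test-set report from [evaluate_model()]),
#'   `model`, `split`, `mask` (feature-filter mask), `blocks`, `dataset`.
#' @export
run_pcm_experiment <- function(table, corpus, alignment,
                               mode = c("control", "embedding", "bow",
                                        "metadata", "multitask"),
                               split_method = "random", test_fraction = 0.1,
                               seed = 42L, embedding_dim = 64L,
                               spec = boosting_spec(),
                               min_cluster_size = 16L) {
  mode <- match.arg(mode)
  desc_of_assay <- assay_context_from_corpus(corpus)

  if (mode == "multitask") {
    emb <- embed_descriptions(corpus,
                              hash_projection_embedder(embedding_dim, seed))
    tm <- fit_topic_model(corpus, emb,
                          cluster_config(min_cluster_size = min_cluster_size,
                                         seed = seed), n_repeats = 1L)[[1L]]
    ds <- aggregate_measurements(table, "cluster",
                                 assay_context_from_model(tm, corpus))
    pairs <- unique(ds[, c("compound_id", "smiles", "target_accession")])
    pair_key <- paste(pairs$compound_id, pairs$target_accession, sep = "\r")
    tasks <- sort(unique(ds$context_id))
    Y <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(tasks),
                dimnames = list(NULL, tasks))
    ridx <- match(paste(ds$compound_id, ds$target_accession, sep = "\r"),
                  pair_key)
    Y[cbind(ridx, match(ds$context_id, tasks))] <- ds$pchembl
    pair_ds <- structure(cbind(pairs, context_id = NA_character_,
                               pchembl = rowMeans(Y, na.rm = TRUE)),
                         mode = "control", class = c("aggregated_dataset",
                                                     "data.frame"))
    fm <- build_feature_matrix(pair_ds, alignment)
    if (length(fm$failed_rows)) Y <- Y[-fm$failed_rows, , drop = FALSE]
    split <- split_dataset(pair_ds[setdiff(seq_len(nrow(pair_ds)),
                                           fm$failed_rows), , drop = FALSE],
                           split_method, test_fraction, seed)
    mask <- apply_feature_filters(fm$x[split$train_idx, , drop = FALSE])
    xtr <- fm$x[split$train_idx, mask, drop = FALSE]
    xte <- fm$x[split$test_idx, mask, drop = FALSE]
    model <- train_multitask(xtr, Y[split$train_idx, , drop = FALSE],
                             spec = spec, seed = seed)
    metrics <- evaluate_model(model, xte, Y[split$test_idx, , drop = FALSE])
    return(list(metrics = metrics, model = model, split = split,
                mask = mask, blocks = fm$blocks[mask], dataset = pair_ds))
  }

  assay_block <- NULL
  if (mode == "control") {
    ds <- aggregate_measurements(table, "control")
  } else {
    ds <- aggregate_measurements(table, "description", desc_of_assay)
    uniq_desc <- unique(trimws(corpus$description))
    first_row <- match(uniq_desc, trimws(corpus$description))
    block <- switch(mode,
      embedding = {
        emb <- embed_descriptions(corpus,
                                  hash_projection_embedder(embedding_dim,
                                                           seed))
        unclass(emb)[first_row, , drop = FALSE]
      },
      bow = {
        bw <- build_bow_fingerprint(corpus)$matrix
        unclass(bw)[first_row, , drop = FALSE]
      },
      metadata = {
        md <- build_metadata_fingerprint(corpus,
                                         select_metadata_properties(corpus))
        unclass(md)[first_row, , drop = FALSE]
      })
    rownames(block) <- uniq_desc
    assay_block <- block
  }
  fm <- build_feature_matrix(ds, alignment, assay_block = assay_block)
  keep_rows <- setdiff(seq_len(nrow(ds)), fm$failed_rows)
  split <- split_dataset(ds[keep_rows, , drop = FALSE], split_method,
                         test_fraction, seed)
  mask <- apply_feature_filters(fm$x[split$train_idx, , drop = FALSE])
  xtr <- fm$x[split$train_idx, mask, drop = FALSE]
  xte <- fm$x[split$test_idx, mask, drop = FALSE]
  model <- train_single_task(xtr, fm$y[split$train_idx], spec, seed)
  metrics <- evaluate_model(model, xte, fm$y[split$test_idx])
  list(metrics = metrics, model = model, split = split, mask = mask,
       blocks = fm$blocks[mask], dataset = ds)
}
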