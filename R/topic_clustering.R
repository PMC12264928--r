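# Topic clustering of unique assay descriptions: dimensionality reduction of
# the description embeddings, density-based clustering with an outlier label,
# class-based TF-IDF term weighting, topic-word extraction, and c-TF-IDF
# based outlier reassignment.

#' Clustering configuration
#'
#' Bundles the tunables of the topic pipeline. `n_components` is the target
#' dimension of the reduction (5, the usual choice for density clustering of
#' text embeddings); `n_neighbors` and `min_dist` parameterize
#' neighborhood-based reducers and are recorded for provenance even when the
#' configured reducer does not use them; `min_cluster_size` is the smallest
#' admissible density cluster (the scan in this package's experiments covers
#' 16, 32, 64 and 128, any value >= 2 is accepted); `supervision_labels`
#' switches the reduction to semisupervised mode with categorical targets
#' (`NA` = unlabeled); `outlier_reduction` controls whether unassigned
#' descriptions are reassigned via c-TF-IDF similarity.
#'
#' @param n_components Reduced dimension (>= 2, default 5).
#' @param n_neighbors Neighborhood size (default 15).
#' @param min_dist Minimum embedded distance (default 0.1).
#' @param min_cluster_size Minimum density-cluster size (default 16).
#' @param supervision_labels Optional categorical vector aligned to corpus
#'   records for semisupervised reduction.
#' @param outlier_reduction Reassign outliers (default TRUE).
#' @param seed Integer seed for the pipeline.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(n_components = 5L, n_neighbors = 15L,
                           min_dist = 0.1, min_cluster_size = 16L,
                           supervision_labels = NULL,
                           outlier_reduction = TRUE, seed = 42L) {
  stopifnot(n_components >= 2L, min_cluster_size >= 2L)
  structure(list(n_components = as.integer(n_components),
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist,
                 min_cluster_size = as.integer(min_cluster_size),
                 supervision_labels = supervision_labels,
                 outlier_reduction = isTRUE(outlier_reduction),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Reduce description embeddings to a low-dimensional space
#'
#' Projects the embedding matrix of unique descriptions onto its first
#' `n_components` principal directions (centered SVD) with a deterministic
#' sign convention, so identical inputs always give identical outputs. In
#' semisupervised mode the configured categorical targets are appended as a
#' one-hot block scaled to the total variance of the embedding block before
#' the decomposition, pulling same-label descriptions together; records with
#' `NA` labels contribute an all-zero block (unlabeled).
#'
#' @param embeddings Numeric matrix, one row per unique description.
#' @param config A [cluster_config()]; `supervision_labels`, when present,
#'   must here be aligned to the rows of `embeddings`.
#' @return Matrix `nrow(embeddings) x n_components`.
#' @export
reduce_embeddings <- function(embeddings, config) {
  stopifnot(is.matrix(embeddings), inherits(config, "cluster_config"))
  n <- nrow(embeddings)
  if (n < config$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 = ", config$n_neighbors + 1L,
         " rows; got ", n, ". Use a smaller n_neighbors.")
  x <- scale(embeddings, center = TRUE, scale = FALSE)
  if (!is.null(config$supervision_labels)) {
    lab <- config$supervision_labels
    stopifnot(length(lab) == n)
    lv <- sort(unique(lab[!is.na(lab)]))
    if (length(lv) >= 2L) {
      oh <- matrix(0, n, length(lv))
      hit <- match(lab, lv)
      idx <- which(!is.na(hit))
      oh[cbind(idx, hit[idx])] <- 1
      oh <- scale(oh, center = TRUE, scale = FALSE)
      v_emb <- sum(apply(x, 2, stats::var))
      v_oh <- sum(apply(oh, 2, stats::var))
      if (v_oh > 0) oh <- oh * sqrt(v_emb / v_oh)
      x <- cbind(x, oh)
    }
  }
  k <- min(config$n_components, ncol(x), n)
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(sv$v[, j]))
    if (sv$v[piv, j] < 0) scores[, j] <- -scores[, j]
  }
  if (k < config$n_components)
    scores <- cbind(scores, matrix(0, n, config$n_components - k))
  unname(scores)
}

# ---- density clustering -----------------------------------------------------

# Density clustering in the reduced space: mutual-reachability single linkage
# with condensed-tree leaf extraction. Core distance of a point is the
# distance to its min_cluster_size-th nearest neighbour; the single-linkage
# dendrogram over mutual reachability distances is condensed by treating a
# split as real only when both sides hold at least min_cluster_size points,
# and the leaves of that condensed tree become the clusters. The root is
# never selected, so data with no internal density structure come back as
# all outliers.

#' Density-cluster a reduced embedding matrix
#'
#' Labels each row with a cluster id `0..K-1` (relabeled by descending
#' cluster size) or `-1` for outliers (low-density points not belonging to
#' any cluster of at least `min_cluster_size` members).
#'
#' @param reduced Numeric matrix (rows = unique descriptions).
#' @param min_cluster_size Minimum cluster size (>= 2).
#' @return Integer vector of labels, `-1` = outlier.
#' @export
cluster_reduced <- function(reduced, min_cluster_size) {
  stopifnot(is.matrix(reduced), min_cluster_size >= 2L,
            nrow(reduced) >= min_cluster_size)
  n <- nrow(reduced)
  d <- as.matrix(stats::dist(reduced))
  k <- min(min_cluster_size, n - 1L)
  core <- apply(d, 1L, function(r) sort(r)[k + 1L])  # k-th neighbour, self excluded
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) -m[1] else members[[m[1]]],
                      if (m[2] < 0) -m[2] else members[[m[2]]])
  }
  node_size <- function(j) if (j < 0) 1L else length(members[[j]])
  labels <- rep(-1L, n)
  next_label <- 0L
  clusters <- list()
  # walk a born cluster rooted at merge node `node`; birth members `mem`
  walk <- function(node, mem) {
    cur <- node
    repeat {
      ch <- hc$merge[cur, ]
      sa <- node_size(ch[1]); sb <- node_size(ch[2])
      if (sa >= min_cluster_size && sb >= min_cluster_size) {
        walk(ch[1], members[[ch[1]]])
        walk(ch[2], members[[ch[2]]])
        return(invisible(NULL))
      }
      if (sa >= min_cluster_size) cur <- ch[1]
      else if (sb >= min_cluster_size) cur <- ch[2]
      else {  # no admissible descent: condensed-tree leaf
        clusters[[length(clusters) + 1L]] <<- mem
        return(invisible(NULL))
      }
    }
  }
  # root cluster is not selectable: descend until the first real split
  cur <- n - 1L
  root_split <- NULL
  repeat {
    ch <- hc$merge[cur, ]
    sa <- node_size(ch[1]); sb <- node_size(ch[2])
    if (sa >= min_cluster_size && sb >= min_cluster_size) {
      root_split <- ch; break
    }
    if (sa >= min_cluster_size) cur <- ch[1]
    else if (sb >= min_cluster_size) cur <- ch[2]
    else break
  }
  if (is.null(root_split)) {
    warning("no density structure found: all points labeled as outliers")
    return(labels)
  }
  walk(root_split[1], members[[root_split[1]]])
  walk(root_split[2], members[[root_split[2]]])
  sizes <- vapply(clusters, length, integer(1))
  for (rank in seq_along(clusters)) {
    idx <- order(-sizes)[rank]
    labels[clusters[[idx]]] <- rank - 1L
  }
  labels
}

# ---- class-based TF-IDF -----------------------------------------------------

#' Fit a class-based TF-IDF model
#'
#' Documents of each cluster are concatenated and the weight of token `t` in
#' cluster `c` is `tf(t, c) * log(1 + A / f(t))` (natural log), where
#' `tf(t, c)` counts `t` in cluster `c`'s concatenation, `f(t)` is the total
#' count of `t` over all clusters, and `A` is the mean token count per
#' cluster. Outlier documents (label `-1`) are excluded from fitting; empty
#' clusters are dropped with a warning.
#'
#' @param documents List of token vectors (preprocessed descriptions).
#' @param labels Integer cluster labels aligned to `documents` (`-1` =
#'   outlier).
#' @return A `ctfidf_model`: `vocabulary`, `weights` (clusters x vocabulary),
#'   `cluster_token_totals`, `mean_tokens_per_cluster`.
#' @export
fit_ctfidf <- function(documents, labels) {
  stopifnot(is.list(documents), length(documents) == length(labels))
  keep <- labels != -1L
  if (!any(keep)) stop("no non-outlier cluster to fit on")
  docs <- documents[keep]
  labs <- labels[keep]
  cl_ids <- sort(unique(labs))
  empty <- vapply(cl_ids, function(cl)
    sum(lengths(docs[labs == cl])) == 0L, logical(1))
  if (any(empty)) {
    warning("dropping ", sum(empty), " cluster(s) with no tokens")
    cl_ids <- cl_ids[!empty]
  }
  vocab <- sort(unique(unlist(docs[labs %in% cl_ids])))
  tf <- matrix(0, nrow = length(cl_ids), ncol = length(vocab),
               dimnames = list(as.character(cl_ids), vocab))
  for (i in seq_along(cl_ids)) {
    tok <- unlist(docs[labs == cl_ids[i]])
    tab <- table(tok)
    tf[i, names(tab)] <- as.numeric(tab)
  }
  f_t <- colSums(tf)
  a_mean <- sum(tf) / nrow(tf)
  w <- tf * matrix(log(1 + a_mean / f_t), nrow = nrow(tf),
                   ncol = ncol(tf), byrow = TRUE)
  structure(list(vocabulary = vocab, weights = w,
                 cluster_token_totals = rowSums(tf),
                 mean_tokens_per_cluster = a_mean),
            class = "ctfidf_model")
}

#' Topic words of a fitted c-TF-IDF model
#'
#' @param model A `ctfidf_model`.
#' @param k Number of words per cluster (default 10); clusters with fewer
#'   tokens give shorter lists.
#' @return Named list, one ordered character vector per cluster, descending
#'   weight with lexicographic tie-break.
#' @export
topic_words <- function(model, k = 10L) {
  stopifnot(inherits(model, "ctfidf_model"), k >= 1L)
  out <- lapply(seq_len(nrow(model$weights)), function(i) {
    w <- model$weights[i, ]
    w <- w[w > 0]
    ord <- order(-w, names(w))
    names(w)[ord][seq_len(min(k, length(w)))]
  })
  names(out) <- rownames(model$weights)
  out
}

#' Reassign outlier documents to their most similar cluster
#'
#' Each outlier document is represented as its token-count vector on the
#' model vocabulary and assigned to the cluster whose c-TF-IDF row has the
#' highest cosine similarity, ties broken by the lower cluster id. Documents
#' with no vocabulary overlap go to the largest cluster (by document count),
#' with a message. Non-outlier labels are never changed.
#'
#' @param model A `ctfidf_model` fitted on the non-outlier clusters.
#' @param documents List of token vectors.
#' @param labels Integer labels with `-1` marking outliers.
#' @return Integer labels without `-1`.
#' @export
reassign_outliers <- function(model, documents, labels) {
  stopifnot(inherits(model, "ctfidf_model"),
            length(documents) == length(labels))
  out_idx <- which(labels == -1L)
  if (length(out_idx) == 0L) return(labels)
  cl_ids <- as.integer(rownames(model$weights))
  w <- model$weights
  w_norm <- sqrt(rowSums(w^2))
  sizes <- table(factor(labels[labels != -1L], levels = cl_ids))
  largest <- cl_ids[which.max(as.integer(sizes))]
  n_no_overlap <- 0L
  for (i in out_idx) {
    counts <- table(documents[[i]][documents[[i]] %in% model$vocabulary])
    if (length(counts) == 0L) {
      labels[i] <- largest
      n_no_overlap <- n_no_overlap + 1L
      next
    }
    v <- numeric(ncol(w))
    v[match(names(counts), model$vocabulary)] <- as.numeric(counts)
    sim <- as.numeric(w %*% v) / (w_norm * sqrt(sum(v^2)))
    sim[!is.finite(sim)] <- -Inf
    labels[i] <- cl_ids[which.max(sim)]  # which.max takes first: lower id wins ties
  }
  if (n_no_overlap > 0L)
    message(n_no_overlap,
            " outlier document(s) had no vocabulary overlap; assigned to largest cluster")
  labels
}

# ---- full pipeline ----------------------------------------------------------

#' Fit topic models over an assay corpus
#'
#' Deduplicates descriptions (exact string equality after whitespace
#' trimming), reduces the embedding rows of the unique descriptions,
#' density-clusters the reduced space, fits c-TF-IDF on the preprocessed
#' unique descriptions, optionally reassigns outliers, and extracts topic
#' words. One model is returned per repeat, each with its own derived seed;
#' every record inherits the label of its unique description.
#'
#' @param corpus An `assay_corpus`.
#' @param embeddings A `descriptor_matrix` (kind `embedding`) aligned to the
#'   corpus rows.
#' @param config A [cluster_config()].
#' @param n_repeats Number of repeats (default 3).
#' @return List of `topic_model` objects.
#' @export
fit_topic_model <- function(corpus, embeddings, config = cluster_config(),
                            n_repeats = 3L) {
  stopifnot(inherits(corpus, "assay_corpus"),
            nrow(embeddings) == nrow(corpus))
  desc <- trimws(corpus$description)
  uniq <- unique(desc)
  if (length(uniq) < 2L)
    stop("corpus has a single unique description; cannot cluster one point")
  first_row <- match(uniq, desc)
  emb_u <- unclass(embeddings)[first_row, , drop = FALSE]
  sup_u <- NULL
  if (!is.null(config$supervision_labels)) {
    stopifnot(length(config$supervision_labels) == nrow(corpus))
    sup_u <- config$supervision_labels[first_row]
  }
  docs_u <- .preprocess_many(uniq)
  lapply(seq_len(n_repeats), function(r) {
    seed_r <- config$seed + r - 1L
    cfg_r <- config
    cfg_r$seed <- seed_r
    cfg_r$supervision_labels <- sup_u
    red <- reduce_embeddings(emb_u, cfg_r)
    labels <- cluster_reduced(red, config$min_cluster_size)
    model <- if (any(labels != -1L)) fit_ctfidf(docs_u, labels) else NULL
    reassigned <- rep(FALSE, length(labels))
    if (config$outlier_reduction && !is.null(model) && any(labels == -1L)) {
      reassigned <- labels == -1L
      labels <- reassign_outliers(model, docs_u, labels)
    }
    structure(list(
      labels_unique = labels,
      labels_record = labels[match(desc, uniq)],
      reassigned_unique = reassigned,
      unique_descriptions = uniq,
      documents = docs_u,
      ctfidf = model,
      topic_words = if (!is.null(model)) topic_words(model) else list(),
      config = config, seed = seed_r),
      class = "topic_model")
  })
}

#' @export
print.topic_model <- function(x, ...) {
  k <- length(unique(x$labels_unique[x$labels_unique != -1L]))
  cat("<topic_model> ", length(x$labels_unique), " unique descriptions, ",
      k, " clusters, ", sum(x$labels_unique == -1L), " outliers (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a cluster assignment as TSV
#'
#' One row per corpus record: `assay_id`, `unique_description_id` (index of
#' the record's unique description), `cluster`, `is_reassigned_outlier`.
#'
#' @param model A `topic_model`.
#' @param corpus The `assay_corpus` the model was fitted on.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cluster_assignment <- function(model, corpus, path) {
  stopifnot(inherits(model, "topic_model"))
  desc <- trimws(corpus$description)
  u_id <- match(desc, model$unique_descriptions)
  out <- data.frame(assay_id = corpus$assay_id,
                    unique_description_id = u_id,
                    cluster = model$labels_record,
                    is_reassigned_outlier = model$reassigned_unique[u_id])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write topic words as JSON
#'
#' @param model A `topic_model`.
#' @param path Output JSON path (`{cluster: [words]}`).
#' @return Invisibly, `path`.
#' @export
write_topic_words <- function(model, path) {
  jsonlite::write_json(model$topic_words, path)
  invisible(path)
}
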