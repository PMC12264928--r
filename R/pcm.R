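# Assay-aware proteochemometric regression: measurement aggregation,
# feature assembly (molecule fingerprint | protein z-scales | optional assay
# block), train-only feature filters, random and scaffold splits,
# gradient-boosted single-task and masked multitask models, metrics, and
# split-gain feature importance. The boosting backend is xgboost.

# ---- aggregation ------------------------------------------------------------

#' Assay-context lookup from a topic model
#'
#' @param model A `topic_model`.
#' @param corpus The `assay_corpus` it was fitted on.
#' @return Named character vector `assay_id -> cluster label`.
#' @export
assay_context_from_model <- function(model, corpus) {
  stats::setNames(as.character(model$labels_record), corpus$assay_id)
}

#' Assay-context lookup from descriptions
#'
#' @param corpus An `assay_corpus`.
#' @return Named character vector `assay_id -> trimmed description`.
#' @export
assay_context_from_corpus <- function(corpus) {
  stats::setNames(trimws(corpus$description), corpus$assay_id)
}

#' Aggregate bioactivity measurements for modeling
#'
#' For compound-protein pairs with multiple measurements, the median pChEMBL
#' value is taken over all measurements (`control` mode), over the
#' measurements within the same assay cluster (`cluster` mode, one row per
#' compound-target-cluster), or over the measurements sharing the same assay
#' description (`description` mode). Even-count medians are the midpoint of
#' the two central values. Rows whose `assay_id` cannot be resolved in
#' `context` are dropped with their count recorded.
#'
#' @param table A `bioactivity_table`.
#' @param mode One of `"control"`, `"cluster"`, `"description"`.
#' @param context Named vector `assay_id -> context id`; required for the
#'   `cluster` and `description` modes (see [assay_context_from_model()] and
#'   [assay_context_from_corpus()]).
#' @return An `aggregated_dataset` data frame with columns `compound_id`,
#'   `smiles`, `target_accession`, `context_id` (`NA` in control mode) and
#'   `pchembl`; attributes `mode` and `n_dropped`.
#' @export
aggregate_measurements <- function(table,
                                   mode = c("control", "cluster",
                                            "description"),
                                   context = NULL) {
  mode <- match.arg(mode)
  tab <- as.data.frame(table)
  n_dropped <- 0L
  if (mode == "control") {
    tab$context_id <- NA_character_
  } else {
    if (is.null(context) || is.null(names(context)))
      stop(mode, " mode requires a named assay_id -> context vector")
    ctx <- unname(context[tab$assay_id])
    n_dropped <- sum(is.na(ctx))
    tab <- tab[!is.na(ctx), , drop = FALSE]
    tab$context_id <- as.character(ctx[!is.na(ctx)])
  }
  key <- paste(tab$compound_id, tab$target_accession, tab$context_id,
               sep = "\r")
  med <- tapply(tab$pchembl, key, stats::median)
  first <- tab[!duplicated(key), c("compound_id", "smiles",
                                   "target_accession", "context_id")]
  rownames(first) <- NULL
  out <- first[match(names(med), paste(first$compound_id,
                                       first$target_accession,
                                       first$context_id, sep = "\r")), ]
  out$pchembl <- as.numeric(med)
  rownames(out) <- NULL
  structure(out, mode = mode, n_dropped = n_dropped,
            class = c("aggregated_dataset", "data.frame"))
}

# ---- protein descriptors ----------------------------------------------------

# Hellberg's principal-property z-scales (z1 hydrophilicity, z2 size/bulk,
# z3 polarity/electronic), one triple per amino acid.
.zscales <- matrix(c(
   0.07, -1.73,  0.09,   # A
   0.71, -0.97,  4.13,   # C
   3.64,  1.13,  2.36,   # D
   3.08,  0.39, -0.07,   # E
  -4.92,  1.30,  0.45,   # F
   2.23, -5.36,  0.30,   # G
   2.41,  1.74,  1.11,   # H
  -4.44, -1.68, -1.03,   # I
   2.84,  1.41, -3.14,   # K
  -4.19, -1.03, -0.98,   # L
  -2.49, -0.27, -0.41,   # M
   3.22,  1.45,  0.84,   # N
  -1.22,  0.88,  2.23,   # P
   2.18,  0.53, -1.14,   # Q
   2.88,  2.52, -3.44,   # R
   1.96, -1.63,  0.57,   # S
   0.92, -2.09, -1.40,   # T
  -2.69, -2.53, -1.29,   # V
  -4.75,  3.65,  0.85,   # W
  -1.39,  2.32,  0.01),  # Y
  ncol = 3L, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("z1", "z2", "z3")))

#' Hellberg z-scale table
#'
#' @return The 20 x 3 matrix of published z-scale values (z1, z2, z3) per
#'   amino acid one-letter code.
#' @export
zscale_table <- function() .zscales

.read_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- Biostrings::readAAStringSet(alignment)
  stopifnot(methods::is(alignment, "XStringSet"))
  w <- Biostrings::width(alignment)
  if (length(unique(w)) != 1L)
    stop("aligned sequences must all have equal length")
  alignment
}

#' z-scale descriptor of one aligned protein
#'
#' Per aligned position the residue's three Hellberg z-scale values; gap
#' positions (`-` or `.`) contribute `(0, 0, 0)`, and unknown residue codes
#' are treated as gaps with a warning.
#'
#' @param alignment A FASTA path or `AAStringSet` of pre-aligned sequences.
#' @param accession Sequence name to featurize.
#' @return Numeric vector of length `3 * alignment width`, named
#'   `p<position>_z<1:3>`.
#' @export
featurize_protein <- function(alignment, accession) {
  aln <- .read_alignment(alignment)
  if (!(accession %in% names(aln)))
    stop("accession not in alignment: ", accession)
  chars <- strsplit(as.character(aln[[accession]]), "")[[1]]
  hit <- match(chars, rownames(.zscales))
  unknown <- is.na(hit) & !(chars %in% c("-", "."))
  if (any(unknown))
    warning("unknown residue code(s) treated as gap: ",
            paste(unique(chars[unknown]), collapse = ", "))
  vals <- matrix(0, nrow = length(chars), ncol = 3L)
  ok <- !is.na(hit)
  vals[ok, ] <- .zscales[hit[ok], ]
  out <- as.vector(t(vals))
  names(out) <- paste0("p", rep(seq_along(chars), each = 3L), "_z", 1:3)
  out
}

#' z-scale descriptors for several accessions
#'
#' @inheritParams featurize_protein
#' @param accessions Character vector of sequence names.
#' @return Matrix `length(accessions) x (3 * width)`, rownames = accessions.
#' @export
featurize_proteins <- function(alignment, accessions) {
  aln <- .read_alignment(alignment)
  t(vapply(accessions, function(a) featurize_protein(aln, a),
           numeric(3L * Biostrings::width(aln)[1L])))
}

# ---- feature assembly and filtering ----------------------------------------

#' Assemble the PCM feature matrix
#'
#' Joins, per dataset row, the molecule fingerprint block, the protein
#' z-scale block, and (optionally) an assay-context block looked up by
#' `context_id`. Block membership of every column is recorded for feature
#' attribution.
#'
#' @param dataset An `aggregated_dataset`.
#' @param alignment FASTA path or `AAStringSet` covering all target
#'   accessions.
#' @param assay_block Optional numeric matrix of assay descriptors with
#'   rownames matching the dataset's `context_id` values.
#' @param n_bits Molecule fingerprint length (default 2048).
#' @return List: `x` (numeric feature matrix with column names), `blocks`
#'   (character block label per column: `molecule`, `protein`, `assay`),
#'   `y` (pChEMBL targets), `failed_rows` (indices of rows dropped for
#'   unparsable SMILES).
#' @export
build_feature_matrix <- function(dataset, alignment, assay_block = NULL,
                                 n_bits = 2048L) {
  stopifnot(inherits(dataset, "aggregated_dataset"))
  uniq_smiles <- unique(dataset$smiles)
  mol_u <- featurize_molecules(uniq_smiles, n_bits = n_bits)
  mol <- mol_u[match(dataset$smiles, uniq_smiles), , drop = FALSE]
  prot_u <- featurize_proteins(alignment, unique(dataset$target_accession))
  prot <- prot_u[match(dataset$target_accession, rownames(prot_u)), ,
                 drop = FALSE]
  blocks <- c(rep("molecule", ncol(mol)), rep("protein", ncol(prot)))
  x <- cbind(mol, prot)
  if (!is.null(assay_block)) {
    stopifnot(!is.null(rownames(assay_block)))
    hit <- match(dataset$context_id, rownames(assay_block))
    if (any(is.na(hit)))
      stop("context_id values missing from assay_block rownames: ",
           paste(utils::head(unique(dataset$context_id[is.na(hit)]), 3L),
                 collapse = ", "))
    ab <- assay_block[hit, , drop = FALSE]
    colnames(ab) <- paste0("assay_", seq_len(ncol(ab)))
    x <- cbind(x, ab)
    blocks <- c(blocks, rep("assay", ncol(ab)))
  }
  failed <- which(!stats::complete.cases(x))
  if (length(failed)) {
    x <- x[-failed, , drop = FALSE]
  }
  rownames(x) <- NULL
  list(x = x, blocks = blocks,
       y = if (length(failed)) dataset$pchembl[-failed] else dataset$pchembl,
       failed_rows = failed)
}

#' Train-set variance and correlation feature filters
#'
#' Computed on training rows only. First drops columns whose variance is
#' strictly below `var_threshold`; then walks the surviving columns in order
#' and drops any column whose absolute Pearson correlation with an earlier
#' kept column exceeds `corr_threshold` (the later column of a correlated
#' pair loses).
#'
#' @param train_features Numeric matrix of training rows.
#' @param corr_threshold Correlation cut (default 0.8, strict).
#' @param var_threshold Variance cut (default 0.05, strict).
#' @return Logical column mask (`TRUE` = keep), to be applied to both the
#'   train and the test matrix.
#' @export
apply_feature_filters <- function(train_features, corr_threshold = 0.8,
                                  var_threshold = 0.05) {
  stopifnot(is.matrix(train_features), nrow(train_features) >= 2L)
  v <- apply(train_features, 2L, stats::var)
  mask <- v >= var_threshold
  if (!any(mask)) stop("all columns dropped by the variance filter")
  idx <- which(mask)
  cm <- abs(suppressWarnings(stats::cor(train_features[, idx, drop = FALSE])))
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    keep[j] <- !any(keep[seq_len(j - 1L)] &
                      cm[seq_len(j - 1L), j] > corr_threshold)
  }
  mask[idx] <- keep
  if (!any(mask)) stop("all columns dropped by the filters")
  mask
}

# ---- splits -----------------------------------------------------------------

#' Split a dataset into train and test rows
#'
#' `random` draws test rows uniformly. `scaffold` computes the Bemis-Murcko
#' scaffold key of every molecule and assigns whole scaffold groups to the
#' test side, in seeded random order, until at least `test_fraction` of the
#' rows are reached, so no scaffold ever appears on both sides.
#'
#' @param dataset An `aggregated_dataset` (or data frame with a `smiles`
#'   column for scaffold mode).
#' @param method `"random"` or `"scaffold"`.
#' @param test_fraction Fraction of rows for the test set (default 0.1).
#' @param seed Integer seed.
#' @return A `split_spec` list: `method`, `test_fraction`, `seed`,
#'   `train_idx`, `test_idx` (disjoint, exhaustive), and `scaffolds` in
#'   scaffold mode.
#' @export
split_dataset <- function(dataset, method = c("random", "scaffold"),
                          test_fraction = 0.1, seed = 42L) {
  method <- match.arg(method)
  n <- nrow(dataset)
  if (n < 10L) stop("need at least 10 rows to split")
  scaffolds <- NULL
  if (method == "random") {
    test_idx <- .with_seed(seed, function()
      sort(sample.int(n, max(1L, round(n * test_fraction)))))
  } else {
    scaffolds <- murcko_scaffolds(dataset$smiles)
    scaffolds[is.na(scaffolds)] <- paste0("unparsable_",
                                          which(is.na(scaffolds)))
    groups <- split(seq_len(n), scaffolds)
    if (length(groups) < 2L)
      stop("a single scaffold covers all molecules; scaffold split impossible")
    ord <- .with_seed(seed, function() sample(length(groups)))
    target <- n * test_fraction
    # seeded greedy subset-sum: take whole groups that fit under the target,
    # then close the remaining gap with one final group only if that lands
    # nearer the target than stopping short
    test_groups <- integer(0)
    cur <- 0
    for (g in ord) {
      sz <- length(groups[[g]])
      if (cur + sz <= target) {
        test_groups <- c(test_groups, g)
        cur <- cur + sz
      }
    }
    remaining <- setdiff(ord, test_groups)
    if (cur < target && length(remaining)) {
      sizes <- vapply(groups[remaining], length, integer(1))
      best <- remaining[which.min(abs(cur + sizes - target))]
      if (abs(cur + length(groups[[best]]) - target) < target - cur ||
          cur == 0) {
        test_groups <- c(test_groups, best)
      }
    }
    test_idx <- sort(unlist(groups[test_groups], use.names = FALSE))
    if (length(test_idx) == n)
      stop("scaffold split consumed all rows; test_fraction too high for the scaffold sizes")
  }
  structure(list(method = method, test_fraction = test_fraction,
                 seed = as.integer(seed),
                 train_idx = setdiff(seq_len(n), test_idx),
                 test_idx = test_idx, scaffolds = scaffolds),
            class = "split_spec")
}

# ---- boosting ---------------------------------------------------------------

#' Gradient-boosting hyperparameters
#'
#' Defaults: at most 1000 trees, learning rate 0.1, at least 50 data points
#' per leaf, maximum depth 8, 80% row subsampling per tree, squared-error
#' loss, early stopping on (masked) holdout R-squared with the given
#' patience over a seeded holdout carved from the training rows.
#'
#' @param max_trees,learning_rate,min_points_per_leaf,max_depth,subsample
#'   Boosting hyperparameters.
#' @param holdout_fraction Fraction of training rows for early stopping.
#' @param patience Early-stopping rounds without holdout improvement.
#' @return A `boosting_spec` list.
#' @export
boosting_spec <- function(max_trees = 1000L, learning_rate = 0.1,
                          min_points_per_leaf = 50L, max_depth = 8L,
                          subsample = 0.8, holdout_fraction = 0.1,
                          patience = 20L) {
  stopifnot(max_trees > 0, learning_rate > 0, min_points_per_leaf > 0,
            max_depth > 0, subsample > 0, subsample <= 1)
  structure(list(max_trees = as.integer(max_trees),
                 learning_rate = learning_rate,
                 min_points_per_leaf = as.integer(min_points_per_leaf),
                 max_depth = as.integer(max_depth), subsample = subsample,
                 holdout_fraction = holdout_fraction,
                 patience = as.integer(patience)),
            class = "boosting_spec")
}

# holdout R^2 eval metric (maximized); falls back to -SSE when the holdout
# targets are constant
.r2_eval <- function(preds, dtrain) {
  y <- xgboost::getinfo(dtrain, "label")
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - preds)^2)
  list(metric = "r2", value = if (sst > 0) 1 - sse / sst else -sse)
}

.xgb_fit <- function(x, y, spec, seed) {
  n <- nrow(x)
  n_hold <- max(2L, round(n * spec$holdout_fraction))
  hold <- .with_seed(seed, function() sort(sample.int(n, n_hold)))
  tr <- setdiff(seq_len(n), hold)
  dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
  dhold <- xgboost::xgb.DMatrix(x[hold, , drop = FALSE], label = y[hold])
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = spec$learning_rate, max_depth = spec$max_depth,
                  min_child_weight = spec$min_points_per_leaf,
                  subsample = spec$subsample, nthread = 1L,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = spec$max_trees,
    evals = list(holdout = dhold), custom_metric = .r2_eval,
    maximize = TRUE, early_stopping_rounds = spec$patience, verbose = 0)
  best <- xgboost::xgb.attr(booster, "best_iteration")
  list(booster = booster,
       n_trees = if (!is.null(best)) as.integer(best) else spec$max_trees)
}

#' Train a single-task PCM boosting model
#'
#' Gradient-boosted regression trees under a [boosting_spec()]: squared-error
#' loss, early stopping on the R-squared of a seeded internal holdout carved
#' from the training rows. Deterministic for fixed data and seed.
#'
#' @param features Numeric feature matrix (training rows).
#' @param y Numeric pChEMBL targets.
#' @param spec A [boosting_spec()].
#' @param seed Integer seed (holdout draw and tree subsampling).
#' @return A `pcm_model`; `n_trees` records the realized tree count.
#' @export
train_single_task <- function(features, y, spec = boosting_spec(),
                              seed = 42L) {
  stopifnot(is.matrix(features), length(y) == nrow(features))
  if (any(!is.finite(y))) stop("targets must be finite")
  if (nrow(features) < spec$min_points_per_leaf)
    stop("fewer rows than min_points_per_leaf")
  fit <- .xgb_fit(features, y, spec, seed)
  structure(list(booster = fit$booster, n_trees = fit$n_trees,
                 spec = spec, seed = as.integer(seed),
                 feature_names = colnames(features)),
            class = "pcm_model")
}

#' @export
predict.pcm_model <- function(object, newdata, ...) {
  stats::predict(object$booster, xgboost::xgb.DMatrix(newdata))
}

#' Train a masked multitask PCM boosting model
#'
#' One output per task (assay cluster). The model is trained on the stacked
#' (row, observed-task) representation with a one-hot task block appended to
#' the features, which optimizes exactly the squared error summed over the
#' observed entries of the target matrix: masked entries are absent from the
#' stack and contribute zero loss and zero gradient. Early stopping monitors
#' masked R-squared on a seeded holdout of the stacked rows. With a single
#' fully observed task the stack equals the single-task design (the constant
#' task indicator is dropped), so the model reduces exactly to
#' [train_single_task()].
#'
#' @param features Numeric feature matrix (training rows).
#' @param Y Numeric matrix `rows x tasks`.
#' @param mask Binary matrix like `Y`; 1 = observed. Defaults to
#'   `!is.na(Y)`.
#' @param spec A [boosting_spec()].
#' @param seed Integer seed.
#' @return A `pcm_multitask_model` with a `tasks` vector; predictions via
#'   [predict_multitask()].
#' @export
train_multitask <- function(features, Y, mask = NULL,
                            spec = boosting_spec(), seed = 42L) {
  stopifnot(is.matrix(features), is.matrix(Y), nrow(Y) == nrow(features))
  if (is.null(mask)) mask <- !is.na(Y) * 1L
  mask <- (mask != 0) & !is.na(Y)
  tasks <- colnames(Y)
  if (is.null(tasks)) tasks <- paste0("task_", seq_len(ncol(Y)))
  empty <- colSums(mask) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " task(s) with no observed value")
    Y <- Y[, !empty, drop = FALSE]
    mask <- mask[, !empty, drop = FALSE]
    tasks <- tasks[!empty]
  }
  if (ncol(Y) == 0L) stop("no task with observed values")
  if (ncol(Y) == 1L && all(mask)) {
    single <- train_single_task(features, Y[, 1L], spec, seed)
    return(structure(list(single = single, tasks = tasks,
                          spec = spec, seed = as.integer(seed),
                          n_trees = single$n_trees),
                     class = "pcm_multitask_model"))
  }
  obs <- which(mask, arr.ind = TRUE)
  task_block <- matrix(0, nrow = nrow(obs), ncol = length(tasks),
                       dimnames = list(NULL, paste0("task_", tasks)))
  task_block[cbind(seq_len(nrow(obs)), obs[, 2L])] <- 1
  x_stack <- cbind(features[obs[, 1L], , drop = FALSE], task_block)
  y_stack <- Y[obs]
  fit <- .xgb_fit(x_stack, y_stack, spec, seed)
  structure(list(booster = fit$booster, n_trees = fit$n_trees,
                 tasks = tasks, spec = spec, seed = as.integer(seed),
                 feature_names = colnames(x_stack)),
            class = "pcm_multitask_model")
}

#' Predict all task outputs of a multitask model
#'
#' @param model A `pcm_multitask_model`.
#' @param features Numeric feature matrix.
#' @return Matrix `nrow(features) x n_tasks`.
#' @export
predict_multitask <- function(model, features) {
  stopifnot(inherits(model, "pcm_multitask_model"))
  if (!is.null(model$single)) {
    out <- matrix(predict(model$single, features), ncol = 1L)
    colnames(out) <- model$tasks
    return(out)
  }
  k <- length(model$tasks)
  out <- matrix(NA_real_, nrow = nrow(features), ncol = k,
                dimnames = list(NULL, model$tasks))
  for (t in seq_len(k)) {
    tb <- matrix(0, nrow = nrow(features), ncol = k)
    tb[, t] <- 1
    colnames(tb) <- paste0("task_", model$tasks)
    out[, t] <- stats::predict(model$booster,
                               xgboost::xgb.DMatrix(cbind(features, tb)))
  }
  out
}

#' Masked R-squared
#'
#' `1 - SSE/SST` over the observed entries only (mask = 1); with a full mask
#' this is the plain R-squared.
#'
#' @param y_true,y_pred Numeric vectors or matrices of equal shape.
#' @param mask Binary object of the same shape; defaults to all-observed.
#' @return The masked R-squared.
#' @export
masked_r2 <- function(y_true, y_pred, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim = if (is.matrix(y_true))
    dim(y_true) else length(y_true))
  obs <- which(mask != 0 & !is.na(y_true))
  if (length(obs) < 2L) stop("need at least 2 observed entries")
  yt <- y_true[obs]; yp <- y_pred[obs]
  sst <- sum((yt - mean(yt))^2)
  if (sst == 0) stop("observed targets have zero variance")
  1 - sum((yt - yp)^2) / sst
}

# ---- evaluation -------------------------------------------------------------

.single_metrics <- function(y, p) {
  c(r2 = 1 - sum((y - p)^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean((y - p)^2)),
    kendall_tau = suppressWarnings(stats::cor(y, p, method = "kendall")))
}

#' Evaluate a trained PCM model on a test set
#'
#' Reports R-squared, RMSE and Kendall's Tau (the tie-corrected tau-b). For
#' multitask models metrics are computed per task over the observed test
#' entries; tasks with fewer than 2 observed test points are excluded (with
#' a message) and a task-size-weighted average row is added.
#'
#' @param model A `pcm_model` or `pcm_multitask_model`.
#' @param features_test Numeric feature matrix of test rows.
#' @param targets_test Numeric vector (single-task) or matrix (multitask).
#' @param mask Optional binary matrix of observed test entries (multitask).
#' @return A data frame with columns `task`, `r2`, `rmse`, `kendall_tau`,
#'   `n`; multitask reports one row per task plus a `"weighted"` row.
#' @export
evaluate_model <- function(model, features_test, targets_test, mask = NULL) {
  if (inherits(model, "pcm_model")) {
    p <- predict(model, features_test)
    m <- .single_metrics(targets_test, p)
    return(data.frame(task = "all", r2 = m["r2"], rmse = m["rmse"],
                      kendall_tau = m["kendall_tau"],
                      n = length(targets_test), row.names = NULL))
  }
  stopifnot(inherits(model, "pcm_multitask_model"), is.matrix(targets_test))
  if (is.null(mask)) mask <- !is.na(targets_test)
  preds <- predict_multitask(model, features_test)
  rows <- list()
  for (t in seq_along(model$tasks)) {
    obs <- which(mask[, t] != 0 & !is.na(targets_test[, t]))
    if (length(obs) < 2L) {
      message("task ", model$tasks[t],
              " has < 2 observed test points; excluded")
      next
    }
    m <- .single_metrics(targets_test[obs, t], preds[obs, t])
    rows[[length(rows) + 1L]] <- data.frame(
      task = model$tasks[t], r2 = m["r2"], rmse = m["rmse"],
      kendall_tau = m["kendall_tau"], n = length(obs), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) > 0L) {
    w <- out$n / sum(out$n)
    out <- rbind(out, data.frame(
      task = "weighted", r2 = sum(w * out$r2), rmse = sum(w * out$rmse),
      kendall_tau = sum(w * out$kendall_tau), n = sum(out$n)))
  }
  out
}

#' Summarize metric reports over repeats
#'
#' @param reports List of data frames from [evaluate_model()].
#' @return Data frame with per-task mean and standard deviation of each
#'   metric over the repeats.
#' @export
summarize_metrics <- function(reports) {
  all <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]; r$repeat_id <- i; r
  }))
  out <- do.call(rbind, lapply(split(all, all$task), function(d) {
    data.frame(task = d$task[1L],
               r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               kendall_tau_mean = mean(d$kendall_tau),
               kendall_tau_sd = stats::sd(d$kendall_tau),
               n = d$n[1L], n_repeats = nrow(d), row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Split-gain feature importance with block attribution
#'
#' Per-feature cumulative squared-error-reduction gain recorded while the
#' trees were grown, with each feature attributed to its descriptor block
#' (molecule, protein, assay). Unused features have importance 0 and are not
#' listed. Block proportions over the top-`top_k` features sum to 1.
#'
#' @param model A `pcm_model` or `pcm_multitask_model`.
#' @param blocks Character vector labeling every training feature column
#'   with its block (as returned by [build_feature_matrix()]); multitask
#'   one-hot task columns are attributed to block `"task"` automatically.
#' @param top_k Number of features in the block-proportion summary
#'   (default 30).
#' @return Data frame `feature`, `gain`, `block`, sorted by descending gain,
#'   with a `block_proportions` attribute over the top `top_k` rows.
#' @export
feature_importance <- function(model, blocks = NULL, top_k = 30L) {
  booster <- if (!is.null(model$single)) model$single$booster
             else model$booster
  feat_names <- if (!is.null(model$single)) model$single$feature_names
                else model$feature_names
  tree <- xgboost::xgb.model.dt.tree(model = booster)
  splits <- tree[tree$Feature != "Leaf", ]
  gain <- tapply(splits$Gain, splits$Feature, sum)
  out <- data.frame(feature = names(gain), gain = as.numeric(gain),
                    row.names = NULL)
  if (!is.null(blocks)) {
    lbl <- stats::setNames(
      c(blocks, rep("task", max(0L, length(feat_names) - length(blocks)))),
      feat_names)
    out$block <- unname(lbl[out$feature])
  } else out$block <- NA_character_
  out <- out[order(-out$gain), , drop = FALSE]
  rownames(out) <- NULL
  top <- utils::head(out, top_k)
  attr(out, "block_proportions") <- table(factor(top$block)) / nrow(top)
  out
}
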