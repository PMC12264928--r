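# Scoring of cluster assignments against categorical labels: purity,
# normalized purity, entropy-based homogeneity/completeness/V-measure,
# adjusted mutual information (permutation-model expectation), and the
# Fowlkes-Mallows index. All entropies use the natural logarithm; every
# reported ratio is base-invariant.

# Keep only records where both the cluster and the category are known.
.paired_labels <- function(assignment, categories) {
  stopifnot(length(assignment) == length(categories))
  keep <- !is.na(assignment) & !is.na(categories)
  if (!any(keep)) stop("no records with both a cluster and a category")
  list(k = as.character(assignment[keep]), c = as.character(categories[keep]))
}

.contingency <- function(assignment, categories) {
  p <- .paired_labels(assignment, categories)
  table(cluster = p$k, category = p$c)
}

#' Cluster purity
#'
#' The fraction of records whose category matches the dominant category of
#' their cluster: the sum over clusters of the largest category count,
#' divided by the number of labeled records.
#'
#' @param assignment Cluster labels (any atomic type; `NA` excluded pairwise).
#' @param categories Category labels aligned to `assignment`.
#' @return Purity in `[0, 1]`.
#' @export
purity <- function(assignment, categories) {
  ct <- .contingency(assignment, categories)
  sum(apply(ct, 1L, max)) / sum(ct)
}

#' Normalized purity
#'
#' Purity min-max scaled by the prevalence of the modal category:
#' `(purity - p_modal) / (1 - p_modal)`. It is 1 when every cluster is pure
#' and 0 when the clustering enriches no label over the corpus-wide modal
#' baseline; values below 0 indicate a clustering worse than that baseline.
#'
#' @inheritParams purity
#' @return Normalized purity (at most 1, possibly negative).
#' @export
normalized_purity <- function(assignment, categories) {
  ct <- .contingency(assignment, categories)
  p_modal <- max(colSums(ct)) / sum(ct)
  if (p_modal >= 1)
    stop("degenerate label set: modal category prevalence is 1")
  (sum(apply(ct, 1L, max)) / sum(ct) - p_modal) / (1 - p_modal)
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Homogeneity, completeness and V-measure
#'
#' Entropy-based agreement between a clustering and a category labeling.
#' Homogeneity `h = 1 - H(C|K)/H(C)` is 1 when each cluster holds a single
#' category; completeness `c = 1 - H(K|C)/H(K)` is 1 when each category sits
#' in a single cluster; V is their harmonic mean. By convention `h = 1` when
#' `H(C) = 0` and `c = 1` when `H(K) = 0`.
#'
#' @inheritParams purity
#' @return Named numeric vector `c(homogeneity, completeness, v_measure)`.
#' @export
homogeneity_completeness_v <- function(assignment, categories) {
  ct <- .contingency(assignment, categories)
  n <- sum(ct)
  h_c <- .entropy(colSums(ct))
  h_k <- .entropy(rowSums(ct))
  # conditional entropies from the joint table
  h_c_given_k <- sum(apply(ct, 1L, function(row) {
    if (sum(row) == 0) 0 else sum(row) / n * .entropy(row)
  }))
  h_k_given_c <- sum(apply(ct, 2L, function(col) {
    if (sum(col) == 0) 0 else sum(col) / n * .entropy(col)
  }))
  h <- if (h_c == 0) 1 else 1 - h_c_given_k / h_c
  cc <- if (h_k == 0) 1 else 1 - h_k_given_c / h_k
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  c(homogeneity = h, completeness = cc, v_measure = v)
}

# Expected mutual information under the permutation (hypergeometric) model.
.expected_mi <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct)
  b <- colSums(ct)
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) +
          lgamma(n - a[i] + 1) + lgamma(n - b[j] + 1) -
          lgamma(n + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) -
          lgamma(b[j] - nij + 1) - lgamma(n - a[i] - b[j] + nij + 1)
        emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) * exp(lp)
      }
    }
  }
  emi
}

.mutual_information <- function(ct) {
  n <- sum(ct)
  mi <- 0
  a <- rowSums(ct); b <- colSums(ct)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  mi
}

#' Adjusted mutual information
#'
#' Chance-corrected agreement between two labelings:
#' `(MI - E[MI]) / (mean(H(C), H(K)) - E[MI])`, with the expectation taken
#' under the permutation model (hypergeometric fixed-margin null). Identical
#' labelings score 1; independent labelings score about 0. A vanishing
#' denominator (both labelings trivial) is defined as 0 with a warning.
#'
#' @inheritParams purity
#' @return AMI (at most 1).
#' @export
adjusted_mutual_information <- function(assignment, categories) {
  ct <- .contingency(assignment, categories)
  mi <- .mutual_information(ct)
  emi <- .expected_mi(ct)
  h_k <- .entropy(rowSums(ct))
  h_c <- .entropy(colSums(ct))
  denom <- (h_k + h_c) / 2 - emi
  if (abs(denom) < 1e-12) {
    warning("AMI denominator is 0; returning 0")
    return(0)
  }
  unname((mi - emi) / denom)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall over all record pairs:
#' `TP / sqrt((TP + FP) (TP + FN))`, where a true positive is a pair placed
#' together by both labelings.
#'
#' @inheritParams purity
#' @return FM index in `[0, 1]`; 0 (with a warning) when a denominator term
#'   vanishes.
#' @export
fowlkes_mallows <- function(assignment, categories) {
  ct <- .contingency(assignment, categories)
  if (sum(ct) < 2L) stop("need at least 2 labeled records")
  tp <- sum(choose(ct, 2))
  tp_fp <- sum(choose(rowSums(ct), 2))
  tp_fn <- sum(choose(colSums(ct), 2))
  if (tp_fp == 0 || tp_fn == 0) {
    warning("Fowlkes-Mallows denominator is 0; returning 0")
    return(0)
  }
  tp / sqrt(tp_fp * tp_fn)
}

#' Evaluate topic models against categorical label sets
#'
#' Computes purity, normalized purity, homogeneity/completeness/V-measure,
#' AMI and Fowlkes-Mallows for every repeat in `models`, every label set,
#' and every level of an optional record-level split (e.g. assay type, to
#' score binding and functional assays separately). Per metric, records with
#' a missing label are excluded pairwise. Metrics are summarized as mean and
#' standard deviation over repeats.
#'
#' @param models List of `topic_model` objects (repeats).
#' @param label_sets Named list of categorical vectors aligned to the corpus
#'   records the models were fitted on.
#' @param split_by Optional categorical vector aligned to records; metrics
#'   are computed separately per level (plus the pooled `"all"` level).
#' @return Data frame with columns `label_set`, `split`, `metric`, `mean`,
#'   `sd`, `n_records`, `n_repeats`.
#' @export
evaluate_against_labels <- function(models, label_sets, split_by = NULL) {
  stopifnot(is.list(models), length(models) >= 1L,
            is.list(label_sets), !is.null(names(label_sets)))
  n_rec <- length(models[[1L]]$labels_record)
  splits <- list(all = rep(TRUE, n_rec))
  if (!is.null(split_by)) {
    stopifnot(length(split_by) == n_rec)
    for (lv in sort(unique(split_by[!is.na(split_by)])))
      splits[[as.character(lv)]] <- !is.na(split_by) & split_by == lv
  }
  rows <- list()
  for (ls_name in names(label_sets)) {
    labels <- label_sets[[ls_name]]
    stopifnot(length(labels) == n_rec)
    for (sp_name in names(splits)) {
      sel <- splits[[sp_name]]
      per_repeat <- lapply(models, function(m) {
        a <- m$labels_record[sel]
        cc <- labels[sel]
        if (all(is.na(cc))) return(NULL)
        hcv <- homogeneity_completeness_v(a, cc)
        np <- tryCatch(normalized_purity(a, cc), error = function(e) NA_real_)
        c(purity = purity(a, cc), normalized_purity = np,
          hcv, ami = adjusted_mutual_information(a, cc),
          fowlkes_mallows = fowlkes_mallows(a, cc),
          n = sum(!is.na(a) & !is.na(cc)))
      })
      per_repeat <- per_repeat[!vapply(per_repeat, is.null, logical(1))]
      if (length(per_repeat) == 0L) {
        message("label set '", ls_name, "' fully missing on split '",
                sp_name, "'; omitted")
        next
      }
      vals <- do.call(rbind, per_repeat)
      metrics <- setdiff(colnames(vals), "n")
      rows[[length(rows) + 1L]] <- data.frame(
        label_set = ls_name, split = sp_name, metric = metrics,
        mean = apply(vals[, metrics, drop = FALSE], 2L, mean),
        sd = if (nrow(vals) > 1L)
          apply(vals[, metrics, drop = FALSE], 2L, stats::sd)
          else rep(0, length(metrics)),
        n_records = vals[1L, "n"], n_repeats = nrow(vals),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation report
#'
#' @param report Data frame from [evaluate_against_labels()].
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_evaluation_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows", digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report)
}
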