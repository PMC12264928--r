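# Deviation between repeated measurements of the same protein-compound pair,
# overall and within assay clusters. The statistic is the size-weighted mean
# of per-group mean absolute deviations about the group mean; groups with a
# single measurement carry no deviation information and are excluded.

#' Mean absolute deviation about the mean
#'
#' @param values Numeric vector of at least two pChEMBL values.
#' @return `mean(|x_i - mean(x)|)`, in pChEMBL units.
#' @export
mean_absolute_deviation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  mean(abs(values - mean(values)))
}

#' Size-weighted mean absolute deviation over replicate groups
#'
#' Groups the table's pChEMBL values by the given key columns, drops groups
#' of size 1, and returns the weighted mean of per-group MADs with weight
#' equal to the group size (so every measurement contributes equally).
#'
#' @param table A `bioactivity_table`, or any data frame with a `pchembl`
#'   column and the key columns.
#' @param keys Character vector of grouping column names, e.g.
#'   `c("target_accession", "compound_id")`.
#' @return List: `value` (the weighted MAD), `groups` (per-group data frame
#'   with key, size and MAD), `n_points` (measurements in groups of size
#'   >= 2), `n_groups`.
#' @export
weighted_group_mad <- function(table, keys = c("target_accession",
                                               "compound_id")) {
  stopifnot(all(keys %in% names(table)))
  key <- do.call(paste, c(lapply(keys, function(k) table[[k]]), sep = "\r"))
  sizes <- table(key)
  big <- names(sizes)[sizes >= 2L]
  if (length(big) == 0L) stop("no replicate group of size >= 2")
  sel <- key %in% big
  mads <- tapply(table$pchembl[sel], key[sel], mean_absolute_deviation)
  ns <- as.numeric(table(key[sel])[names(mads)])
  groups <- data.frame(key = names(mads), size = ns,
                       mad = as.numeric(mads), row.names = NULL)
  list(value = sum(groups$mad * groups$size) / sum(groups$size),
       groups = groups, n_points = sum(ns), n_groups = nrow(groups))
}

#' Replicate-deviation report, overall and within assay clusters
#'
#' The overall statistic groups measurements by (target, compound); the
#' within-cluster statistic additionally conditions on the assay cluster of
#' each measurement (joined via `assay_id` to each topic model's record
#' labels) and is summarized as mean and standard deviation over the
#' clustering repeats. When the clusters capture real between-assay offsets,
#' the within-cluster deviation falls below the overall one. An optional
#' per-family breakdown repeats both statistics per protein family.
#'
#' @param table A `bioactivity_table`.
#' @param models List of `topic_model` objects (repeats).
#' @param corpus The `assay_corpus` the models were fitted on (provides the
#'   `assay_id` to cluster join).
#' @param family_labels Optional named vector mapping `target_accession` to
#'   a protein-family label.
#' @return A `deviation_report` list: `overall_weighted_mad`,
#'   `within_cluster_weighted_mad` (`mean`, `sd`, `per_repeat`), counts,
#'   `n_unjoinable`, and optionally `per_family`.
#' @export
deviation_report <- function(table, models, corpus, family_labels = NULL) {
  stopifnot(inherits(table, "bioactivity_table"), is.list(models),
            inherits(corpus, "assay_corpus"))
  tab <- as.data.frame(table)
  joinable <- !is.na(tab$assay_id) & tab$assay_id %in% corpus$assay_id
  n_unjoinable <- sum(!joinable)
  tab <- tab[joinable, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows joinable to the corpus via assay_id")
  row_of_assay <- match(tab$assay_id, corpus$assay_id)

  overall <- weighted_group_mad(tab)
  per_repeat <- vapply(models, function(m) {
    tab$cluster <- m$labels_record[row_of_assay]
    res <- tryCatch(
      weighted_group_mad(tab, c("target_accession", "compound_id", "cluster")),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$value
  }, numeric(1))

  report <- list(
    overall_weighted_mad = overall$value,
    overall_n_groups = overall$n_groups,
    overall_n_points = overall$n_points,
    within_cluster_weighted_mad = list(
      mean = if (all(is.na(per_repeat))) NA_real_
             else mean(per_repeat, na.rm = TRUE),
      sd = if (sum(!is.na(per_repeat)) > 1L) stats::sd(per_repeat, na.rm = TRUE)
           else 0,
      per_repeat = per_repeat),
    n_unjoinable = n_unjoinable)

  if (!is.null(family_labels)) {
    fam <- family_labels[tab$target_accession]
    report$per_family <- lapply(
      stats::setNames(nm = sort(unique(fam[!is.na(fam)]))), function(f) {
        sub <- tab[!is.na(fam) & fam == f, , drop = FALSE]
        ov <- tryCatch(weighted_group_mad(sub), error = function(e) NULL)
        wr <- vapply(models, function(m) {
          sub$cluster <- m$labels_record[match(sub$assay_id, corpus$assay_id)]
          res <- tryCatch(weighted_group_mad(
            sub, c("target_accession", "compound_id", "cluster")),
            error = function(e) NULL)
          if (is.null(res)) NA_real_ else res$value
        }, numeric(1))
        list(overall = if (is.null(ov)) NA_real_ else ov$value,
             within_cluster_mean = if (all(is.na(wr))) NA_real_
                                   else mean(wr, na.rm = TRUE))
      })
  }
  class(report) <- "deviation_report"
  report
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("<deviation_report>\n")
  cat(sprintf("  overall weighted MAD: %.4f (%d groups, %d points)\n",
              x$overall_weighted_mad, x$overall_n_groups, x$overall_n_points))
  cat(sprintf("  within-cluster weighted MAD: %.4f +/- %.4f (%d repeats)\n",
              x$within_cluster_weighted_mad$mean,
              x$within_cluster_weighted_mad$sd,
              sum(!is.na(x$within_cluster_weighted_mad$per_repeat))))
  if (x$n_unjoinable > 0)
    cat("  unjoinable rows excluded:", x$n_unjoinable, "\n")
  invisible(x)
}

#' Write a deviation report as JSON (and per-group table as TSV)
#'
#' @param report A `deviation_report`.
#' @param json_path Output JSON path.
#' @param groups,groups_path Optional per-group data frame (from
#'   [weighted_group_mad()]) and its TSV path.
#' @return Invisibly, `json_path`.
#' @export
write_deviation_report <- function(report, json_path, groups = NULL,
                                   groups_path = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!is.null(groups) && !is.null(groups_path))
    utils::write.table(groups, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(json_path)
}
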