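# Reading, validation and filtering of ChEMBL-style assay-metadata tables and
# Papyrus-style bioactivity tables into the package's data model.

.assay_fields <- c("assay_id", "description", "assay_type", "bao_format",
                   "standard_type", "tax_id", "confidence_score",
                   "relationship_type", "src_id", "curated_by", "pref_name")
.assay_mandatory <- c("assay_id", "description")

.bio_fields <- c("compound_id", "smiles", "target_accession", "pchembl",
                 "assay_id", "standard_type", "quality_flag", "censored",
                 "mw", "document_id")
.bio_mandatory <- c("compound_id", "smiles", "target_accession", "pchembl")

# CSV/TSV dialect by extension, overridable
.read_table_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    quote = if (sep == ",") "\"" else "")
}

.add_provenance <- function(x, note) {
  attr(x, "provenance") <- c(attr(x, "provenance"), note)
  x
}

#' Provenance notes of a corpus or table
#'
#' @param x An `assay_corpus` or `bioactivity_table`.
#' @return Character vector: source file and every applied filter with its
#'   parameters and removal counts, in order.
#' @export
provenance <- function(x) attr(x, "provenance")

new_assay_corpus <- function(records, provenance = character(0)) {
  stopifnot(is.data.frame(records))
  structure(records, provenance = provenance,
            class = c("assay_corpus", "data.frame"))
}

#' @export
print.assay_corpus <- function(x, ...) {
  cat("<assay_corpus> ", nrow(x), " records, ",
      length(unique(trimws(x$description))), " unique descriptions\n", sep = "")
  for (p in provenance(x)) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Read an assay-metadata table
#'
#' Reads a ChEMBL-style assay export (CSV/TSV with a header row) into an
#' `assay_corpus`. `column_map` maps the package's field names (`assay_id`,
#' `description`, `assay_type`, `bao_format`, `standard_type`, `tax_id`,
#' `confidence_score`, `relationship_type`, `src_id`, `curated_by`,
#' `pref_name`) to the file's column names; unmapped optional fields default
#' to their own name and become `NA` when absent from the header. Rows with a
#' missing description are rejected (dropped, counted in provenance);
#' duplicated `assay_id` values are an error.
#'
#' @param path Path to the table.
#' @param column_map Named character vector, `field = "column name"`.
#' @param sep Field separator; default auto-detects by extension
#'   (`.csv` comma, otherwise tab).
#' @return An `assay_corpus` (data frame with a provenance attribute).
#' @export
read_assay_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- .read_table_auto(path, sep)
  map <- stats::setNames(.assay_fields, .assay_fields)
  if (!is.null(column_map)) {
    stopifnot(!is.null(names(column_map)))
    bad <- setdiff(names(column_map), .assay_fields)
    if (length(bad)) stop("unknown field(s) in column_map: ",
                          paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
    # explicitly mapped columns must exist
    missing_mapped <- column_map[!(column_map %in% names(raw))]
    if (length(missing_mapped))
      stop("schema error: mapped column(s) absent from header: ",
           paste(missing_mapped, collapse = ", "))
  }
  for (f in .assay_mandatory) {
    if (!(map[[f]] %in% names(raw)))
      stop("schema error: mandatory column missing: ", map[[f]],
           " (field ", f, ")")
  }
  rec <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    assay_id = as.character(raw[[map[["assay_id"]]]]),
                    description = as.character(raw[[map[["description"]]]]))
  for (f in setdiff(.assay_fields, .assay_mandatory)) {
    col <- map[[f]]
    rec[[f]] <- if (col %in% names(raw)) as.character(raw[[col]])
                else NA_character_
  }
  n_missing_desc <- sum(is.na(rec$description) | !nzchar(trimws(rec$description)))
  if (n_missing_desc > 0L)
    rec <- rec[!(is.na(rec$description) | !nzchar(trimws(rec$description))), ,
               drop = FALSE]
  dup <- unique(rec$assay_id[duplicated(rec$assay_id)])
  if (length(dup))
    stop("integrity error: duplicated assay_id: ", paste(dup, collapse = ", "))
  prov <- c(sprintf("read %d records from %s", nrow(rec), path),
            if (n_missing_desc > 0L)
              sprintf("rejected %d records with missing description",
                      n_missing_desc))
  new_assay_corpus(rec, prov)
}

#' Filter an assay corpus by description length and assay type
#'
#' Keeps records whose assay type is in `allowed_assay_types` and whose
#' description, after trimming surrounding whitespace, has at most
#' `max_description_chars` Unicode characters ("more than 500 characters" is a
#' strict rule: a 500-character description is retained). Removal counts per
#' rule are appended to the provenance.
#'
#' @param corpus An `assay_corpus`.
#' @param max_description_chars Maximum retained description length (default
#'   500 characters).
#' @param allowed_assay_types Retained assay-type codes (default binding `B`
#'   and functional `F`).
#' @return The filtered `assay_corpus` (possibly empty, with a warning).
#' @export
filter_assay_corpus <- function(corpus, max_description_chars = 500L,
                                allowed_assay_types = c("B", "F")) {
  stopifnot(inherits(corpus, "assay_corpus"))
  if (nrow(corpus) == 0L) stop("corpus is empty")
  desc_len <- nchar(trimws(corpus$description), type = "chars")
  keep_len <- desc_len <= max_description_chars
  keep_type <- corpus$assay_type %in% allowed_assay_types
  out <- corpus[keep_len & keep_type, , drop = FALSE]
  prov <- c(provenance(corpus),
            sprintf("filter: description length > %d removed %d records",
                    max_description_chars, sum(!keep_len)),
            sprintf("filter: assay_type not in {%s} removed %d records",
                    paste(allowed_assay_types, collapse = ","),
                    sum(!keep_type & keep_len)))
  if (nrow(out) == 0L) warning("all records removed by filters")
  new_assay_corpus(as.data.frame(out), prov)
}

#' Write an assay corpus as TSV
#'
#' @param corpus An `assay_corpus`.
#' @param path Output TSV path.
#' @param provenance_path Optional path for the provenance notes as JSON.
#' @return Invisibly, `path`.
#' @export
write_assay_corpus <- function(corpus, path, provenance_path = NULL) {
  stopifnot(inherits(corpus, "assay_corpus"))
  utils::write.table(as.data.frame(corpus), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(provenance_path))
    jsonlite::write_json(provenance(corpus), provenance_path,
                         auto_unbox = FALSE)
  invisible(path)
}

# ---- bioactivity ------------------------------------------------------------

new_bioactivity_table <- function(points, provenance = character(0),
                                  rejects = NULL) {
  structure(points, provenance = provenance, rejects = rejects,
            class = c("bioactivity_table", "data.frame"))
}

#' @export
print.bioactivity_table <- function(x, ...) {
  cat("<bioactivity_table> ", nrow(x), " points, ",
      length(unique(x$target_accession)), " targets, ",
      length(unique(x$compound_id)), " compounds\n", sep = "")
  for (p in provenance(x)) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Rejected rows of the last read
#'
#' @param x A `bioactivity_table`.
#' @return Data frame of rejected input rows with a `reject_reason` column,
#'   or `NULL`.
#' @export
rejects <- function(x) attr(x, "rejects")

#' Read a bioactivity table
#'
#' Reads a Papyrus-style bioactivity table into a `bioactivity_table` of
#' (compound, target, assay) measurements on the pChEMBL scale. SMILES are
#' stored verbatim; standardization happens at featurization time. Rows with
#' an unparsable pChEMBL value on an uncensored measurement are diverted to a
#' rejects report (see [rejects()]) rather than aborting the read.
#'
#' @param path Path to the table.
#' @param column_map Named character vector mapping the fields `compound_id`,
#'   `smiles`, `target_accession`, `pchembl`, `assay_id`, `standard_type`,
#'   `quality_flag`, `censored`, `mw` to column names.
#' @param sep Field separator (auto by extension when `NULL`).
#' @return A `bioactivity_table`.
#' @export
read_bioactivity_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- .read_table_auto(path, sep)
  map <- stats::setNames(.bio_fields, .bio_fields)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .bio_fields)
    if (length(bad)) stop("unknown field(s) in column_map: ",
                          paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
    missing_mapped <- column_map[!(column_map %in% names(raw))]
    if (length(missing_mapped))
      stop("schema error: mapped column(s) absent from header: ",
           paste(missing_mapped, collapse = ", "))
  }
  for (f in .bio_mandatory) {
    if (!(map[[f]] %in% names(raw)))
      stop("schema error: mandatory column missing: ", map[[f]],
           " (field ", f, ")")
  }
  getcol <- function(f, default = NA_character_) {
    col <- map[[f]]
    if (col %in% names(raw)) as.character(raw[[col]]) else
      rep(default, nrow(raw))
  }
  pts <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    compound_id = getcol("compound_id"),
    smiles = getcol("smiles"),
    target_accession = getcol("target_accession"),
    pchembl = suppressWarnings(as.numeric(getcol("pchembl"))),
    assay_id = getcol("assay_id"),
    standard_type = getcol("standard_type"),
    quality_flag = getcol("quality_flag"),
    censored = tolower(getcol("censored", "false")) %in% c("true", "1", "t"),
    mw = suppressWarnings(as.numeric(getcol("mw"))),
    document_id = getcol("document_id"))
  bad_pchembl <- !pts$censored & !is.finite(pts$pchembl)
  bad_target <- is.na(pts$target_accession) | !nzchar(pts$target_accession)
  bad <- bad_pchembl | bad_target
  rej <- NULL
  if (any(bad)) {
    rej <- pts[bad, , drop = FALSE]
    rej$reject_reason <- ifelse(bad_pchembl[bad],
                                "unparsable pchembl on uncensored row",
                                "empty target_accession")
    pts <- pts[!bad, , drop = FALSE]
  }
  prov <- c(sprintf("read %d points from %s (%d rejected)",
                    nrow(pts), path, sum(bad)))
  new_bioactivity_table(pts, prov, rej)
}

.is_low_quality <- function(flag) {
  !is.na(flag) & grepl("low", flag, ignore.case = TRUE)
}

#' Filter a bioactivity table
#'
#' Row-level rules (any order): drop low-quality rows (quality flag matching
#' "low"), drop censored rows, drop rows with molecular weight strictly over
#' `max_mw` Da. The target-level rule is applied last, after all row-level
#' filters: only targets with strictly more than
#' `min_unique_compounds_per_target` unique compounds are kept. Removal
#' counts per rule are recorded in the provenance.
#'
#' @param table A `bioactivity_table`.
#' @param max_mw Maximum molecular weight in Da (default 1000); rows with
#'   unknown weight are retained.
#' @param min_unique_compounds_per_target Strict lower bound on unique
#'   compounds per target (default 100).
#' @param drop_low_quality,drop_censored Enable/disable the respective rule.
#' @param exclude_documents Optional character vector of document/publication
#'   identifiers whose data points are removed (e.g. publications describing
#'   allosteric modulators); matched against the `document_id` field.
#' @return The filtered `bioactivity_table`.
#' @export
filter_bioactivity <- function(table, max_mw = 1000,
                               min_unique_compounds_per_target = 100L,
                               drop_low_quality = TRUE, drop_censored = TRUE,
                               exclude_documents = NULL) {
  stopifnot(inherits(table, "bioactivity_table"))
  if (nrow(table) == 0L) stop("table is empty")
  prov <- provenance(table)
  keep <- rep(TRUE, nrow(table))
  if (drop_low_quality) {
    low <- .is_low_quality(table$quality_flag)
    prov <- c(prov, sprintf("filter: low quality removed %d points",
                            sum(low & keep)))
    keep <- keep & !low
  }
  if (drop_censored) {
    prov <- c(prov, sprintf("filter: censored removed %d points",
                            sum(table$censored & keep)))
    keep <- keep & !table$censored
  }
  if (!is.null(exclude_documents) && !is.null(table$document_id)) {
    excl <- !is.na(table$document_id) & table$document_id %in% exclude_documents
    prov <- c(prov, sprintf("filter: excluded documents removed %d points",
                            sum(excl & keep)))
    keep <- keep & !excl
  }
  heavy <- !is.na(table$mw) & table$mw > max_mw
  prov <- c(prov, sprintf("filter: mw > %g Da removed %d points",
                          max_mw, sum(heavy & keep)))
  keep <- keep & !heavy
  out <- as.data.frame(table)[keep, , drop = FALSE]
  # target-level rule, strictly-more-than, applied last
  n_cpd <- tapply(out$compound_id, out$target_accession,
                  function(x) length(unique(x)))
  ok_targets <- names(n_cpd)[n_cpd > min_unique_compounds_per_target]
  removed <- sum(!(out$target_accession %in% ok_targets))
  prov <- c(prov, sprintf(
    "filter: targets with <= %d unique compounds removed %d points",
    min_unique_compounds_per_target, removed))
  out <- out[out$target_accession %in% ok_targets, , drop = FALSE]
  if (nrow(out) == 0L) warning("all points removed by filters")
  new_bioactivity_table(out, prov)
}

#' Write a bioactivity table as TSV
#'
#' @param table A `bioactivity_table`.
#' @param path Output TSV path.
#' @param provenance_path Optional JSON path for provenance notes.
#' @param rejects_path Optional TSV path for the rejects report.
#' @return Invisibly, `path`.
#' @export
write_bioactivity_table <- function(table, path, provenance_path = NULL,
                                    rejects_path = NULL) {
  stopifnot(inherits(table, "bioactivity_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(provenance_path))
    jsonlite::write_json(provenance(table), provenance_path)
  if (!is.null(rejects_path) && !is.null(rejects(table)))
    utils::write.table(rejects(table), rejects_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' pChEMBL value of a molar activity
#'
#' The pChEMBL value puts heterogeneous activity readouts (IC50, EC50, Ki,
#' KD) on one unitless log scale: the negative base-10 logarithm of the molar
#' concentration or affinity constant. A 1 micromolar IC50 maps to 6.0.
#'
#' @param value Positive activity value in molar units (vectorized).
#' @return `-log10(value)`.
#' @export
compute_pchembl <- function(value) {
  if (any(!is.finite(value) | value <= 0))
    stop("activity values must be positive and finite (molar units)")
  -log10(value)
}
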