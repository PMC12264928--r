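# Assay descriptor families: metadata one-hot fingerprints, bag-of-words
# fingerprints over preprocessed descriptions, and dense embeddings behind a
# pluggable embedder contract.

new_descriptor_matrix <- function(values, kind, feature_names = NULL,
                                  embedder_name = NULL) {
  stopifnot(is.matrix(values),
            kind %in% c("metadata_fp", "bow_fp", "embedding"))
  if (kind != "embedding") {
    stopifnot(length(feature_names) == ncol(values),
              all(values %in% c(0, 1)))
  }
  structure(values, kind = kind, feature_names = feature_names,
            embedder_name = embedder_name,
            class = c("descriptor_matrix", "matrix", "array"))
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix> kind=", attr(x, "kind"), ", ", nrow(x), " x ",
      ncol(x), "\n", sep = "")
  invisible(x)
}

#' Kind of a descriptor matrix
#' @param x A `descriptor_matrix`.
#' @return One of `"metadata_fp"`, `"bow_fp"`, `"embedding"`.
#' @export
descriptor_kind <- function(x) attr(x, "kind")

# ---- metadata fingerprints --------------------------------------------------

.metadata_properties <- c("relationship_type", "standard_type", "src_id",
                          "confidence_score", "bao_format", "curated_by",
                          "assay_type", "tax_id", "pref_name")

#' Select metadata properties suitable for one-hot fingerprinting
#'
#' A property qualifies when its non-missing coverage over the corpus is at
#' least `required_coverage` and it has at most `max_categories` unique
#' categories. With the defaults (full coverage, 40 categories) this
#' reproduces the rule that selects relationship type, standard type, src id,
#' confidence score, BAO format, curated by, and assay type on a ChEMBL-style
#' export. Properties are returned in a fixed canonical order.
#'
#' @param corpus An `assay_corpus`.
#' @param required_coverage Minimum fraction of records with a defined value
#'   (default 1.0 = the property must be defined everywhere).
#' @param max_categories Maximum number of unique categories (default 40).
#' @return Character vector of property names (possibly empty).
#' @export
select_metadata_properties <- function(corpus, required_coverage = 1.0,
                                       max_categories = 40L) {
  stopifnot(inherits(corpus, "assay_corpus"), nrow(corpus) > 0L)
  ok <- vapply(.metadata_properties, function(p) {
    v <- corpus[[p]]
    if (is.null(v)) return(FALSE)
    coverage <- mean(!is.na(v))
    n_cat <- length(unique(v[!is.na(v)]))
    coverage >= required_coverage && n_cat <= max_categories && n_cat >= 1L
  }, logical(1))
  .metadata_properties[ok]
}

#' Build a metadata one-hot fingerprint
#'
#' One one-hot block per property; within each record every property block
#' sums to exactly 1. Feature names are `property=category`. When `levels`
#' (from a previously built fingerprint) are supplied, the new matrix uses
#' exactly those columns; records carrying a category unseen at build time
#' get an all-zero block for that property, with a warning.
#'
#' @param corpus An `assay_corpus` on which the properties are fully defined
#'   (unless `levels` is given).
#' @param properties Character vector of property names, e.g. from
#'   [select_metadata_properties()].
#' @param levels Optional named list `property -> category levels` to apply a
#'   trained fingerprint to new records.
#' @return A `descriptor_matrix` of kind `metadata_fp`; its `"levels"`
#'   attribute holds the per-property category levels.
#' @export
build_metadata_fingerprint <- function(corpus, properties, levels = NULL) {
  stopifnot(inherits(corpus, "assay_corpus"), length(properties) > 0L)
  if (is.null(levels)) {
    for (p in properties) {
      if (any(is.na(corpus[[p]])))
        stop("property not fully defined on corpus: ", p)
    }
    levels <- lapply(stats::setNames(properties, properties),
                     function(p) sort(unique(corpus[[p]])))
  }
  blocks <- lapply(properties, function(p) {
    lv <- levels[[p]]
    v <- corpus[[p]]
    unseen <- !is.na(v) & !(v %in% lv)
    if (any(unseen))
      warning(sprintf("property %s: %d record(s) carry categories unseen at build time; all-zero block emitted",
                      p, sum(unseen)))
    m <- matrix(0, nrow = nrow(corpus), ncol = length(lv),
                dimnames = list(NULL, paste0(p, "=", lv)))
    hit <- match(v, lv)
    idx <- which(!is.na(hit))
    m[cbind(idx, hit[idx])] <- 1
    m
  })
  values <- do.call(cbind, blocks)
  out <- new_descriptor_matrix(values, "metadata_fp",
                               feature_names = colnames(values))
  attr(out, "levels") <- levels
  out
}

# ---- bag-of-words fingerprints ---------------------------------------------

#' Build a bag-of-words fingerprint over assay descriptions
#'
#' Descriptions are preprocessed ([preprocess_description()]); the vocabulary
#' is the top `max_bits` tokens by document frequency (number of records
#' whose description contains the token), ties broken lexicographically. The
#' matrix is binary presence/absence. When fewer distinct tokens exist than
#' `max_bits` the vocabulary is simply all tokens. Supplying `vocabulary`
#' (a spec returned by a previous call) rebuilds the matrix bit-exactly
#' without re-selecting terms.
#'
#' @param corpus An `assay_corpus`.
#' @param max_bits Vocabulary cap (default 1024).
#' @param language_stopwords,assay_stopwords Passed to
#'   [preprocess_description()].
#' @param vocabulary Optional vocabulary spec to reuse.
#' @return List with `matrix` (a `descriptor_matrix` of kind `bow_fp`, with a
#'   `mean_bits_per_record` attribute) and `vocabulary` (terms plus a record
#'   of the preprocessing rules).
#' @export
build_bow_fingerprint <- function(corpus, max_bits = 1024L,
                                  language_stopwords = english_stopwords(),
                                  assay_stopwords = assaycontext::assay_stopwords(),
                                  vocabulary = NULL) {
  stopifnot(inherits(corpus, "assay_corpus"), nrow(corpus) > 0L)
  toks <- .preprocess_many(corpus$description,
                           language_stopwords = language_stopwords,
                           assay_stopwords = assay_stopwords)
  if (is.null(vocabulary)) {
    df_counts <- table(unlist(lapply(toks, unique)))
    ord <- order(-as.integer(df_counts), names(df_counts))
    terms <- names(df_counts)[ord]
    if (length(terms) > max_bits) terms <- terms[seq_len(max_bits)]
    vocabulary <- list(
      terms = terms,
      preprocessing = list(stemmer = "porter",
                           token_rule = "alphanumeric runs >= 2 chars",
                           stopword_order = "before stemming",
                           selection = "top document frequency, ties lexicographic",
                           max_bits = as.integer(max_bits)))
  }
  terms <- vocabulary$terms
  values <- matrix(0, nrow = nrow(corpus), ncol = length(terms),
                   dimnames = list(NULL, terms))
  for (i in seq_along(toks)) {
    hit <- match(unique(toks[[i]]), terms)
    hit <- hit[!is.na(hit)]
    if (length(hit)) values[i, hit] <- 1
  }
  mat <- new_descriptor_matrix(values, "bow_fp", feature_names = terms)
  attr(mat, "mean_bits_per_record") <- mean(rowSums(values))
  list(matrix = mat, vocabulary = vocabulary)
}

# ---- embedding contract -----------------------------------------------------

#' Construct an embedder specification
#'
#' An embedder is a list contract: a `name`, a fixed output `dimension`, a
#' maximum accepted input length in characters, a determinism flag, and an
#' `embed(texts)` function returning one row per input text. Adapters for
#' pretrained language models plug in through this contract; the package
#' itself ships the deterministic [hash_projection_embedder()].
#'
#' @param name Embedder name (recorded on descriptor matrices).
#' @param dimension Output dimension (positive integer).
#' @param embed Function: character vector -> numeric matrix
#'   `length(texts) x dimension`.
#' @param max_input_chars Longest accepted description (default 500).
#' @param deterministic Whether identical text always embeds identically.
#' @return An `embedder_spec` list.
#' @export
embedder_spec <- function(name, dimension, embed, max_input_chars = 500L,
                          deterministic = TRUE) {
  stopifnot(is.function(embed), dimension >= 2L)
  structure(list(name = name, dimension = as.integer(dimension),
                 embed = embed, max_input_chars = as.integer(max_input_chars),
                 deterministic = isTRUE(deterministic)),
            class = "embedder_spec")
}

# deterministic 32-bit-safe string/int hashing (Horner mod prime)
.hash_mod <- 2146435069
.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 127 + b) %% .hash_mod
  h
}
.hash_ints <- function(ints) {
  h <- 0
  for (b in ints) h <- (h * 1000003 + (b %% .hash_mod)) %% .hash_mod
  h
}

# evaluate f with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

# hashed 4096-bucket token-count vector of a preprocessed text
.hashed_counts <- function(text, n_buckets = 4096L) {
  toks <- preprocess_description(text)
  v <- numeric(n_buckets)
  if (length(toks)) {
    idx <- vapply(toks, function(t) (.hash_string(t) %% n_buckets) + 1,
                  numeric(1))
    tab <- table(idx)
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v
}

#' Deterministic hash-projection embedder
#'
#' A fully offline, deterministic text embedder: the description is
#' preprocessed, token counts are hashed into 4096 buckets, and the count
#' vector is projected through a seeded Gaussian random matrix
#' (4096 x `dimension`) and L2-normalized. Random Gaussian projections
#' approximately preserve cosine geometry, so texts sharing vocabulary embed
#' nearby; this makes the embedder a faithful stand-in for a pretrained
#' language model wherever only the geometry of the embedding space matters.
#'
#' @param dimension Output dimension (>= 2).
#' @param seed Integer seed fixing the projection matrix.
#' @return An `embedder_spec` named `hash_projection_<dimension>_<seed>`.
#' @export
hash_projection_embedder <- function(dimension, seed) {
  stopifnot(dimension >= 2L)
  n_buckets <- 4096L
  proj <- .with_seed(seed, function()
    matrix(stats::rnorm(n_buckets * dimension), nrow = n_buckets))
  embed <- function(texts) {
    counts <- t(vapply(texts, .hashed_counts, numeric(n_buckets),
                       USE.NAMES = FALSE))
    out <- counts %*% proj
    nrm <- sqrt(rowSums(out^2))
    nz <- nrm > 0
    out[nz, ] <- out[nz, , drop = FALSE] / nrm[nz]
    out
  }
  embedder_spec(name = sprintf("hash_projection_%d_%d", dimension, seed),
                dimension = dimension, embed = embed)
}

#' Embed assay descriptions
#'
#' Each unique description (after whitespace trimming) is embedded exactly
#' once and the result broadcast to every record sharing it. Descriptions
#' longer than the embedder's `max_input_chars` are an error: upstream
#' filtering is expected to have removed them.
#'
#' @param corpus An `assay_corpus`.
#' @param embedder An `embedder_spec`.
#' @return A `descriptor_matrix` of kind `embedding` with
#'   `corpus-rows x dimension` values.
#' @export
embed_descriptions <- function(corpus, embedder) {
  stopifnot(inherits(corpus, "assay_corpus"), inherits(embedder, "embedder_spec"))
  desc <- trimws(corpus$description)
  too_long <- nchar(desc, type = "chars") > embedder$max_input_chars
  if (any(too_long))
    stop("description(s) exceed embedder max_input_chars (",
         embedder$max_input_chars, "): record(s) ",
         paste(utils::head(corpus$assay_id[too_long], 5L), collapse = ", "))
  uniq <- unique(desc)
  emb <- embedder$embed(uniq)
  if (!is.matrix(emb) || nrow(emb) != length(uniq) ||
      ncol(emb) != embedder$dimension)
    stop("embedder contract violated: expected ", length(uniq), " x ",
         embedder$dimension, " matrix")
  if (any(!is.finite(emb))) {
    bad <- which(!is.finite(rowSums(emb)))[1L]
    stop("embedder failure on description of record ",
         corpus$assay_id[match(uniq[bad], desc)])
  }
  values <- emb[match(desc, uniq), , drop = FALSE]
  rownames(values) <- NULL
  new_descriptor_matrix(values, "embedding", embedder_name = embedder$name)
}

# ---- descriptor matrix IO ---------------------------------------------------

#' Write a descriptor matrix with a JSON sidecar
#'
#' The dense values go to a TSV; the sidecar records the kind, feature names
#' or embedder name, and a fingerprint hash of the corpus descriptions so a
#' matrix cannot silently be applied to a different corpus.
#'
#' @param x A `descriptor_matrix`.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @param corpus Optional `assay_corpus` used to compute the corpus hash.
#' @return Invisibly, `path`.
#' @export
write_descriptor_matrix <- function(x, path, corpus = NULL) {
  stopifnot(inherits(x, "descriptor_matrix"))
  utils::write.table(unclass(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(x)))
  meta <- list(kind = attr(x, "kind"),
               n_rows = nrow(x), n_cols = ncol(x),
               feature_names = attr(x, "feature_names"),
               embedder_name = attr(x, "embedder_name"))
  if (!is.null(corpus))
    meta$corpus_hash <- .hash_ints(vapply(trimws(corpus$description),
                                          .hash_string, numeric(1)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptor_matrix()]
#'
#' @param path TSV path (sidecar expected at `<path>.json`).
#' @return A `descriptor_matrix`.
#' @export
read_descriptor_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  has_header <- !is.null(meta$feature_names) && length(meta$feature_names) > 0
  values <- as.matrix(utils::read.delim(path, header = has_header,
                                        check.names = FALSE))
  if (has_header) colnames(values) <- meta$feature_names
  new_descriptor_matrix(values, meta$kind,
                        feature_names = meta$feature_names,
                        embedder_name = meta$embedder_name)
}
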