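# Independently written brute-force oracles and small fixture builders.
# The oracles deliberately use naive loop-based formulations so they share
# no code path with the package implementations they check.

# c-TF-IDF by direct definition: per-cluster token counts, global counts,
# mean tokens per cluster, weight = tf * log(1 + A / f)
oracle_ctfidf <- function(documents, labels) {
  keep <- labels != -1L
  documents <- documents[keep]
  labels <- labels[keep]
  clusters <- sort(unique(labels))
  vocab <- sort(unique(unlist(documents)))
  tf <- matrix(0, length(clusters), length(vocab),
               dimnames = list(as.character(clusters), vocab))
  for (i in seq_along(documents)) {
    r <- match(labels[i], clusters)
    for (tok in documents[[i]]) tf[r, tok] <- tf[r, tok] + 1
  }
  a_mean <- sum(tf) / length(clusters)
  w <- tf
  for (j in seq_len(ncol(tf))) {
    f <- sum(tf[, j])
    for (i in seq_len(nrow(tf))) w[i, j] <- tf[i, j] * log(1 + a_mean / f)
  }
  w
}

oracle_purity <- function(k, c) {
  total <- 0
  for (cl in unique(k)) {
    counts <- table(c[k == cl])
    total <- total + max(counts)
  }
  total / length(k)
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

oracle_hcv <- function(k, c) {
  n <- length(k)
  hc <- oracle_entropy(c); hk <- oracle_entropy(k)
  h_c_k <- 0
  for (cl in unique(k)) {
    sel <- k == cl
    h_c_k <- h_c_k + sum(sel) / n * oracle_entropy(c[sel])
  }
  h_k_c <- 0
  for (cat in unique(c)) {
    sel <- c == cat
    h_k_c <- h_k_c + sum(sel) / n * oracle_entropy(k[sel])
  }
  h <- if (hc == 0) 1 else 1 - h_c_k / hc
  cc <- if (hk == 0) 1 else 1 - h_k_c / hk
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  c(h, cc, v)
}

oracle_mi <- function(k, c) {
  n <- length(k)
  mi <- 0
  for (cl in unique(k)) for (cat in unique(c)) {
    nij <- sum(k == cl & c == cat)
    if (nij > 0)
      mi <- mi + nij / n * log(n * nij / (sum(k == cl) * sum(c == cat)))
  }
  mi
}

# hypergeometric expected MI by direct summation with factorials on the
# log scale
oracle_emi <- function(k, c) {
  n <- length(k)
  a <- as.numeric(table(k)); b <- as.numeric(table(c))
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n); hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      logp <- lfactorial(ai) + lfactorial(bj) + lfactorial(n - ai) +
        lfactorial(n - bj) - lfactorial(n) - lfactorial(nij) -
        lfactorial(ai - nij) - lfactorial(bj - nij) -
        lfactorial(n - ai - bj + nij)
      emi <- emi + nij / n * log(n * nij / (ai * bj)) * exp(logp)
    }
  }
  emi
}

oracle_ami <- function(k, c) {
  mi <- oracle_mi(k, c); emi <- oracle_emi(k, c)
  denom <- (oracle_entropy(k) + oracle_entropy(c)) / 2 - emi
  (mi - emi) / denom
}

# Fowlkes-Mallows by O(n^2) pair enumeration
oracle_fm <- function(k, c) {
  n <- length(k)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_k <- k[i] == k[j]; same_c <- c[i] == c[j]
    if (same_k && same_c) tp <- tp + 1
    else if (same_k) fp <- fp + 1
    else if (same_c) fn <- fn + 1
  }
  if (tp + fp == 0 || tp + fn == 0) return(0)
  tp / sqrt((tp + fp) * (tp + fn))
}

# random labeling pair over n records
random_labeling <- function(n, k_clusters, k_cats) {
  list(k = sample.int(k_clusters, n, replace = TRUE),
       c = sample.int(k_cats, n, replace = TRUE))
}

# random tiny token corpus with cluster labels
random_token_corpus <- function(n_docs, n_clusters, vocab = letters[1:6]) {
  docs <- lapply(seq_len(n_docs), function(i)
    sample(vocab, sample(1:6, 1), replace = TRUE))
  labels <- sample.int(n_clusters, n_docs, replace = TRUE) - 1L
  list(documents = docs, labels = labels)
}

# small on-disk assay table
write_tiny_assay_tsv <- function(path, n = 3L) {
  df <- data.frame(
    assay_id = paste0("A", seq_len(n)),
    description = paste("displacement of radioligand from receptor", seq_len(n)),
    assay_type = rep(c("B", "F"), length.out = n),
    bao_format = "BAO_0000357", standard_type = "Ki", tax_id = "9606",
    confidence_score = "8", relationship_type = "D", src_id = "1",
    curated_by = "Expert", pref_name = "Receptor X")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

tiny_corpus <- function(descriptions, assay_type = "B", ...) {
  n <- length(descriptions)
  assaycontext:::new_assay_corpus(data.frame(
    assay_id = paste0("A", seq_len(n)), description = descriptions,
    assay_type = rep(assay_type, length.out = n),
    bao_format = rep("BAO_0000357", n), standard_type = rep("Ki", n),
    tax_id = rep("9606", n), confidence_score = rep("8", n),
    relationship_type = rep("D", n), src_id = rep("1", n),
    curated_by = rep("Expert", n), pref_name = rep("Receptor X", n),
    stringsAsFactors = FALSE, ...))
}

# data-frame content without provenance/rejects attributes or row names
plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  attr(x, "rejects") <- NULL
  rownames(x) <- NULL
  x
}

tiny_bioactivity <- function(df) {
  defaults <- list(standard_type = "Ki", quality_flag = "high",
                   censored = FALSE, mw = 350, assay_id = NA_character_,
                   smiles = "c1ccccc1", compound_id = "C1",
                   target_accession = "P1")
  for (f in names(defaults)) if (is.null(df[[f]])) df[[f]] <- defaults[[f]]
  assaycontext:::new_bioactivity_table(df)
}
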