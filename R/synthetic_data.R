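# Synthetic assay corpora and bioactivity tables with known generative
# structure. Archetypes emulate real assay families (radioligand
# displacement, cAMP accumulation, calcium flux, enzyme inhibition,
# transporter uptake): each has a private keyword pool, a shared filler
# vocabulary, archetype-correlated categorical metadata, and an additive
# per-archetype activity offset. Disjoint keyword pools guarantee that the
# archetypes are separable in any embedding that preserves lexical overlap,
# with a known margin, which is what makes recovery experiments
# interpretable.

#' Define an assay archetype
#'
#' @param name Archetype name.
#' @param keyword_pool Tokens unique to the archetype.
#' @param filler_pool Tokens shared across archetypes.
#' @param metadata_distribution Named list: property -> named probability
#'   vector over categories (each summing to 1).
#' @param activity_offset Optional fixed pChEMBL shift; when `NA` the
#'   generator draws one from `N(0, offset_sd^2)`.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(name, keyword_pool, filler_pool,
                           metadata_distribution, activity_offset = NA_real_) {
  for (p in metadata_distribution)
    stopifnot(abs(sum(p) - 1) < 1e-8, !is.null(names(p)))
  structure(list(name = name, keyword_pool = keyword_pool,
                 filler_pool = filler_pool,
                 metadata_distribution = metadata_distribution,
                 activity_offset = activity_offset),
            class = "archetype_spec")
}

.shared_filler <- c(
  "protein", "concentration", "response", "dose", "incubation", "buffer",
  "measured", "measurement", "signal", "plate", "reference", "control",
  "standard", "temperature", "minutes", "hours", "expressing", "transfected",
  "recombinant", "wild", "type", "assessment", "analysis", "value",
  "dependent", "method", "procedure", "sample", "condition", "treatment")

#' Default assay archetypes
#'
#' Five archetypes modeled on common pharmacological assay families, with
#' disjoint keyword pools, a shared filler vocabulary, and
#' archetype-correlated metadata (binding archetypes are mostly assay type B
#' with radioligand-binding BAO formats and Ki/IC50 readouts; functional
#' ones mostly F with cell-based formats and EC50/potency readouts).
#'
#' @param n Number of archetypes, between 2 and 5 (default 5).
#' @return List of [archetype_spec()] objects.
#' @export
default_archetypes <- function(n = 5L) {
  stopifnot(n >= 2L, n <= 5L)
  mk_meta <- function(pb, bao, st) {
    list(assay_type = c(B = pb, F = 1 - pb),
         bao_format = bao, standard_type = st)
  }
  all <- list(
    archetype_spec("radioligand_displacement",
      c("displacement", "radioligand", "3h", "125i", "membranes",
        "scintillation", "counting", "dpcpx", "cgs21680", "binding",
        "affinity", "competition"),
      .shared_filler,
      mk_meta(0.9,
              c("BAO_0000357" = 0.8, "BAO_0000219" = 0.15, "BAO_0000019" = 0.05),
              c(Ki = 0.7, IC50 = 0.3))),
    archetype_spec("camp_accumulation",
      c("camp", "forskolin", "accumulation", "adenylate", "cyclase",
        "stimulation", "agonist", "glosensor", "cre", "luciferase",
        "gs", "gi"),
      .shared_filler,
      mk_meta(0.1,
              c("BAO_0000219" = 0.7, "BAO_0000019" = 0.25, "BAO_0000357" = 0.05),
              c(EC50 = 0.6, IC50 = 0.4))),
    archetype_spec("calcium_flux",
      c("calcium", "flipr", "fluo", "mobilization", "flux", "fura",
        "intracellular", "aequorin", "gq", "ionomycin", "dye", "kinetic"),
      .shared_filler,
      mk_meta(0.1,
              c("BAO_0000219" = 0.8, "BAO_0000019" = 0.15, "BAO_0000357" = 0.05),
              c(EC50 = 0.7, Potency = 0.3))),
    archetype_spec("enzyme_inhibition",
      c("kinase", "phosphorylation", "atp", "substrate", "enzymatic",
        "catalytic", "peptide", "autophosphorylation", "km", "vmax",
        "adp", "glo"),
      .shared_filler,
      mk_meta(0.8,
              c("BAO_0000357" = 0.6, "BAO_0000019" = 0.35, "BAO_0000219" = 0.05),
              c(IC50 = 0.8, Ki = 0.2))),
    archetype_spec("transporter_uptake",
      c("uptake", "transport", "transporter", "efflux", "substrate14c",
        "oocytes", "vesicles", "reuptake", "accumulation3h", "influx",
        "gaba", "monoamine"),
      .shared_filler,
      mk_meta(0.5,
              c("BAO_0000019" = 0.6, "BAO_0000219" = 0.35, "BAO_0000357" = 0.05),
              c(IC50 = 0.5, Km = 0.5))))
  all[seq_len(n)]
}

.check_disjoint_pools <- function(archetypes) {
  pools <- lapply(archetypes, `[[`, "keyword_pool")
  all_kw <- unlist(pools)
  if (anyDuplicated(all_kw))
    stop("config error: archetype keyword pools overlap: ",
         paste(unique(all_kw[duplicated(all_kw)]), collapse = ", "))
}

#' Generate a synthetic assay corpus with known archetypes
#'
#' Each description is 8-20 tokens, roughly 60% drawn (with replacement)
#' from the record's archetype keyword pool and 40% from the shared filler
#' pool, joined with spaces; categorical metadata are sampled from the
#' archetype's distributions. Fully deterministic given the seed.
#'
#' @param archetypes List of [archetype_spec()] (>= 2, disjoint keyword
#'   pools).
#' @param n_per_archetype Records per archetype (>= 2).
#' @param seed Integer seed.
#' @return A `synthetic_corpus`: list with `corpus` (an `assay_corpus`) and
#'   `true_archetype` (one label per record).
#' @export
generate_assay_corpus <- function(archetypes, n_per_archetype, seed = 1L) {
  stopifnot(length(archetypes) >= 2L, n_per_archetype >= 2L)
  .check_disjoint_pools(archetypes)
  gen <- function() {
    rows <- list()
    for (a in archetypes) {
      for (i in seq_len(n_per_archetype)) {
        len <- sample(8:20, 1L)
        n_kw <- round(0.6 * len)
        toks <- c(sample(a$keyword_pool, n_kw, replace = TRUE),
                  sample(a$filler_pool, len - n_kw, replace = TRUE))
        toks <- sample(toks)  # interleave keywords and filler
        meta <- lapply(a$metadata_distribution, function(p)
          sample(names(p), 1L, prob = p))
        rows[[length(rows) + 1L]] <- data.frame(
          description = paste(toks, collapse = " "),
          assay_type = meta$assay_type, bao_format = meta$bao_format,
          standard_type = meta$standard_type,
          tax_id = "9606", confidence_score = sample(7:9, 1L),
          relationship_type = "D", src_id = "1",
          curated_by = "Autocuration",
          pref_name = paste0(a$name, " panel"),
          true_archetype = a$name, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df <- df[sample(nrow(df)), , drop = FALSE]  # shuffle archetype blocks
    df$assay_id <- sprintf("SYN%06d", seq_len(nrow(df)))
    rownames(df) <- NULL
    df
  }
  df <- .with_seed(seed, gen)
  truth <- df$true_archetype
  rec <- df[, c("assay_id", "description", "assay_type", "bao_format",
                "standard_type", "tax_id", "confidence_score",
                "relationship_type", "src_id", "curated_by", "pref_name")]
  rec$confidence_score <- as.character(rec$confidence_score)
  corpus <- new_assay_corpus(rec, sprintf(
    "synthetic corpus: %d archetypes x %d records, seed %d",
    length(archetypes), n_per_archetype, seed))
  structure(list(corpus = corpus, true_archetype = truth),
            class = "synthetic_corpus")
}

.packaged_smiles <- function() {
  path <- system.file("extdata", "druglike_smiles.smi",
                      package = "assaycontext")
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("smiles", "compound_id"))
  tab
}

# mutated copies of a random consensus: equal length, pre-aligned
.synthetic_alignment <- function(n_targets, length_aa = 60L,
                                 mutation_rate = 0.08) {
  aa <- rownames(zscale_table())
  consensus <- sample(aa, length_aa, replace = TRUE)
  seqs <- vapply(seq_len(n_targets), function(i) {
    s <- consensus
    mut <- which(stats::runif(length_aa) < mutation_rate)
    if (length(mut)) s[mut] <- sample(aa, length(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  Biostrings::AAStringSet(stats::setNames(seqs,
                                          sprintf("SYNT%04d", seq_len(n_targets))))
}

#' Generate synthetic bioactivity with additive assay-archetype effects
#'
#' The generative model on the pChEMBL scale is
#' `pchembl(c, t, a) = mu_t + beta_c + delta_archetype(a) + eps` with
#' `mu_t ~ N(6.5, 0.5^2)` per target, `beta_c ~ N(0, 1)` per compound,
#' `delta ~ N(0, offset_sd^2)` drawn once per archetype, and
#' `eps ~ N(0, noise_sd^2)` per measurement. Every compound-target pair is
#' measured in `Poisson(replicate_rate) + 1` assays whose archetypes are
#' sampled uniformly; each measurement links to an assay record of that
#' archetype. Compounds carry valid drug-like SMILES from the packaged list;
#' target proteins are mutated copies of a random consensus (equal length,
#' pre-aligned).
#'
#' @param n_targets Number of protein targets.
#' @param n_compounds_per_target Compounds sampled per target from the
#'   shared compound pool.
#' @param archetypes List of [archetype_spec()].
#' @param replicate_rate Expected extra assays per pair (Poisson rate).
#' @param offset_sd SD of the per-archetype offsets (pChEMBL units).
#' @param noise_sd SD of the measurement noise (pChEMBL units).
#' @param seed Integer seed.
#' @param corpus Optional `synthetic_corpus` to draw assay records from;
#'   generated internally (seed + 1000, 20 records per archetype) when
#'   omitted.
#' @return A `synthetic_bioactivity`: list with `table` (a
#'   `bioactivity_table`), `corpus`, `alignment` (an `AAStringSet`), and
#'   `truth` (all generative parameters).
#' @export
generate_bioactivity <- function(n_targets, n_compounds_per_target,
                                 archetypes = default_archetypes(),
                                 replicate_rate = 2, offset_sd = 0.5,
                                 noise_sd = 0.3, seed = 1L, corpus = NULL) {
  stopifnot(n_targets >= 1L, n_compounds_per_target >= 1L, noise_sd >= 0)
  if (is.null(corpus))
    corpus <- generate_assay_corpus(archetypes, n_per_archetype = 20L,
                                    seed = seed + 1000L)
  stopifnot(inherits(corpus, "synthetic_corpus"))
  arch_names <- vapply(archetypes, `[[`, character(1), "name")
  assays_of <- lapply(stats::setNames(nm = arch_names), function(a)
    which(corpus$true_archetype == a))
  if (any(lengths(assays_of) == 0L))
    stop("corpus carries no records for archetype(s): ",
         paste(arch_names[lengths(assays_of) == 0L], collapse = ", "))
  smiles_pool <- .packaged_smiles()

  out <- .with_seed(seed, function() {
    pool_size <- min(nrow(smiles_pool),
                     max(2L * n_compounds_per_target, n_compounds_per_target))
    pool <- smiles_pool[sample(nrow(smiles_pool), pool_size), ]
    accessions <- sprintf("SYNT%04d", seq_len(n_targets))
    mu_t <- stats::setNames(stats::rnorm(n_targets, 6.5, 0.5), accessions)
    beta_c <- stats::setNames(stats::rnorm(pool_size, 0, 1),
                              pool$compound_id)
    delta <- stats::setNames(vapply(archetypes, function(a)
      if (is.na(a$activity_offset)) stats::rnorm(1L, 0, offset_sd)
      else a$activity_offset, numeric(1)), arch_names)
    aln <- .synthetic_alignment(n_targets)
    rows <- list()
    for (t in accessions) {
      cpd_idx <- sample(pool_size, n_compounds_per_target)
      for (ci in cpd_idx) {
        n_meas <- stats::rpois(1L, replicate_rate) + 1L
        arch <- sample(arch_names, n_meas, replace = TRUE)
        for (m in seq_len(n_meas)) {
          rec_i <- assays_of[[arch[m]]][sample.int(length(assays_of[[arch[m]]]), 1L)]
          rows[[length(rows) + 1L]] <- data.frame(
            compound_id = pool$compound_id[ci],
            smiles = pool$smiles[ci],
            target_accession = t,
            pchembl = mu_t[t] + beta_c[ci] + delta[arch[m]] +
              stats::rnorm(1L, 0, noise_sd),
            assay_id = corpus$corpus$assay_id[rec_i],
            standard_type = corpus$corpus$standard_type[rec_i],
            quality_flag = "high", censored = FALSE,
            mw = round(180 + 9 * nchar(pool$smiles[ci]) +
                         stats::runif(1L, -20, 20), 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(tab = tab, mu_t = mu_t, beta_c = beta_c, delta = delta, aln = aln)
  })
  table <- new_bioactivity_table(out$tab, sprintf(
    "synthetic bioactivity: %d targets x %d compounds, replicate_rate %g, offset_sd %g, noise_sd %g, seed %d",
    n_targets, n_compounds_per_target, replicate_rate, offset_sd, noise_sd,
    seed))
  structure(list(table = table, corpus = corpus, alignment = out$aln,
                 truth = list(mu_t = out$mu_t, beta_c = out$beta_c,
                              delta_archetype = out$delta,
                              noise_sd = noise_sd, offset_sd = offset_sd,
                              replicate_rate = replicate_rate, seed = seed)),
            class = "synthetic_bioactivity")
}

#' Machine-readable ground truth of a synthetic object
#'
#' @param x A `synthetic_corpus` or `synthetic_bioactivity`.
#' @param path Optional JSON output path.
#' @return The truth as a list (invisibly when `path` is given).
#' @export
ground_truth_report <- function(x, path = NULL) {
  truth <- if (inherits(x, "synthetic_corpus")) {
    list(kind = "corpus",
         true_archetype = stats::setNames(as.list(x$true_archetype),
                                          x$corpus$assay_id))
  } else if (inherits(x, "synthetic_bioactivity")) {
    c(list(kind = "bioactivity"), lapply(x$truth, function(v)
      if (!is.null(names(v))) as.list(v) else v))
  } else stop("not a synthetic object")
  if (!is.null(path)) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    return(invisible(truth))
  }
  truth
}
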