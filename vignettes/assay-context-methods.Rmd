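---
title: "Assay-context methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay-context methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science inside `assaycontext`: the models and
procedures, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where several defensible
options existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Aggregated bioactivity data mix measurements from heterogeneous assays.
Repeated measurements of the same compound–protein pair routinely disagree
by amounts far exceeding experimental replicate error, because the assays
differ in readout, system, and protocol. The only broadly available record
of those differences is the assay's free-text description and a few
categorical metadata fields. The package turns that context into
descriptors, groups similar assays into interpretable topics, quantifies
how much between-assay variance the groups explain, and injects the
context into proteochemometric (PCM) regression models.

## Assay descriptors

**Metadata fingerprints.** A categorical property qualifies for one-hot
encoding when it is defined on 100% of the records and has at most 40
unique categories (`select_metadata_properties()`; both thresholds are
arguments). On a typical ChEMBL-style export this selects relationship
type, standard type, src id, confidence score, BAO format, curated by, and
assay type. Each property contributes a one-hot block whose row sums are
exactly 1; at apply time an unseen category yields an all-zero block plus
a warning rather than silently inventing a level.

**Bag-of-words fingerprints.** Descriptions are lowercased and tokenized
into maximal alphanumeric runs of length ≥ 2 — digits are token characters
because radiolabels (`3h`, `125i`) and compound codes (`cgs21680`) are
among the most assay-discriminative vocabulary. Stop words are removed
*before* stemming (standard stop lists hold unstemmed surface forms): the
318-word Glasgow/scikit-learn English list plus a configurable
assay-specific list of generic assay vocabulary (`assay_stopwords()`,
shipped as configuration, not ground truth). Surviving tokens are stemmed
with an internal implementation of Porter's 1980 algorithm, validated in
the tests against hand-traced stems of the algorithm's published examples.
The vocabulary is the top 1024 tokens by document frequency (ties broken
lexicographically) and features are binary presence bits. Presence rather
than counts was chosen because a bit vector is the natural reading of a
fixed-length "fingerprint"; the selection rule (top document frequency) is
the standard choice where none is otherwise dictated.

**Embeddings.** Dense description embeddings enter through an explicit
contract (`embedder_spec`): a fixed dimension, a 500-character input cap
(upstream filtering guarantees it), a determinism flag, and an
`embed(texts)` function. Each *unique* description is embedded exactly
once and broadcast to all records sharing it. Adapters for pretrained
transformer models (e.g. 768- or 1536-dimensional biomedical/general text
encoders) plug in through this contract; the package itself ships
`hash_projection_embedder()`: token counts hashed into 4096 buckets and
projected through a seeded Gaussian matrix, L2-normalized. Random Gaussian
projections approximately preserve cosine geometry (verified by a
Monte-Carlo test against directly computed hashed-count cosines), so the
hash embedder is a faithful, fully offline stand-in wherever only the
geometry of the embedding space matters. What it cannot emulate is
semantic similarity without lexical overlap — two paraphrases sharing no
tokens embed orthogonally — which is exactly the capability a pretrained
language model adds.

## Topic clustering

The pipeline deduplicates descriptions (exact string equality after
whitespace trimming), reduces the unique-description embeddings to
`n_components = 5` dimensions, density-clusters the reduced points with a
minimum cluster size, fits c-TF-IDF, extracts topic words, and optionally
reassigns outliers. Three repeats with derived seeds are the default
reporting unit (mean ± sd).

**Reduction.** The reducer behind `reduce_embeddings()` is a centered
singular value decomposition (PCA) with a deterministic sign convention,
optionally augmented — in semisupervised mode — with a one-hot block of
categorical targets scaled to the variance of the embedding block, which
pulls same-label descriptions together before the decomposition. The
contract (5 output dimensions, determinism given a seed, a semisupervised
option) is what the rest of the pipeline depends on; neighbor-graph
methods such as UMAP satisfy the same contract and can be substituted
where available. A linear reducer concentrates clusters less aggressively
than a manifold method, which is why the package's corpus-size guidance
below matters.

**Density clustering.** `cluster_reduced()` implements
mutual-reachability single linkage with condensed-tree leaf extraction:
the core distance of a point is the distance to its
`min_cluster_size`-th nearest neighbor; pairwise distances are replaced by
`max(d, core_i, core_j)`; the single-linkage dendrogram is condensed by
treating a split as real only when both sides hold at least
`min_cluster_size` points; the leaves of the condensed tree are the
clusters and everything else is an outlier (label −1). The root is never
selectable, so structureless data legitimately come back all-outlier.
Clusters are relabeled `0..K−1` by descending size. The experiments scan
minimum cluster sizes 16, 32, 64, 128; any value ≥ 2 is accepted. Because
the core-distance neighborhood equals the minimum cluster size, groups
barely above that size flatten into chains and dissolve: as a rule of
thumb the pipeline needs roughly 5× `min_cluster_size` unique
descriptions per expected topic (the shipped tests use 200 descriptions
per archetype at minimum size 16).

**c-TF-IDF.** Cluster documents are concatenated and the weight of token
*t* in cluster *c* is `tf(t,c) · log(1 + A / f(t))` with natural
logarithm, `f(t)` the total count of *t* over all clusters and `A` the
mean token count per cluster — the published form of the class-based
TF-IDF statistic used in neural topic modeling. Outlier documents are
excluded from fitting. Topic words are the top-k tokens per cluster by
descending weight, ties lexicographic.

**Outlier reassignment.** An outlier document is represented as its
token-count vector on the model vocabulary and assigned to the cluster
with maximal cosine similarity to that cluster's c-TF-IDF row (ties: lower
cluster id; zero vocabulary overlap: largest cluster, logged).
Reassignment operates at unique-description granularity — all records
sharing a description move together — matching the deduplicated
clustering itself.

## Cluster evaluation

All metrics exclude records with a missing label pairwise (per metric, not
corpus-wide), are invariant to relabeling, and are computed over *records*
rather than unique descriptions, weighting frequent descriptions by their
data volume. Entropies use the natural logarithm; every reported quantity
is a ratio of entropies and therefore base-invariant (asserted in the
tests).

* purity: Σ over clusters of the dominant-category count, / N;
* normalized purity: `(purity − p_modal) / (1 − p_modal)` — 1 for pure
  clusters, 0 at the majority-label baseline, negative below it;
* homogeneity `1 − H(C|K)/H(C)`, completeness `1 − H(K|C)/H(K)`, V their
  harmonic mean, with the degenerate conventions `h = 1` when `H(C) = 0`
  and `c = 1` when `H(K) = 0`;
* adjusted mutual information with the expectation under the permutation
  (hypergeometric) model and the mean-entropy normalizer;
* Fowlkes–Mallows: `TP/√((TP+FP)(TP+FN))` over record pairs.

Each metric is tested against an independently written brute-force oracle
(pair enumeration for Fowlkes–Mallows, direct hypergeometric summation for
the AMI expectation) on random labelings.

## Replicate-variance decomposition

The deviation statistic is the mean absolute deviation about the group
*mean* (the reference point had to be fixed; the mean pairs naturally with
the additive-noise model below), computed per replicate group of repeated
(target, compound) measurements and averaged with weights equal to group
size, so every measurement contributes equally. Groups of size 1 carry no
deviation information and are excluded from numerator and weights. The
within-cluster statistic adds the assay cluster to the group key and is
reported as mean ± sd over clustering repeats; per-family breakdowns are
available alongside the pooled statistic (the pooled form is primary).
When clusters capture real additive between-assay offsets, conditioning on
them shrinks the weighted MAD toward the pure measurement-noise floor —
the synthetic-data tests verify both the direction and, via a Monte-Carlo
oracle for Gaussian noise at the realized group-size mix, the level.

## PCM modeling

**Aggregation.** For pairs with multiple measurements the median pChEMBL
is taken over all measurements (control), over measurements in the same
assay cluster (multitask), or over measurements sharing a description
(assay-descriptor modes). Even-count medians are the midpoint of the two
central values.

**Features.** Molecules: ECFP6-style circular fingerprints — SMILES are
parsed by ChemmineR/OpenBabel, the largest fragment is kept (salt
stripping), atom neighborhoods are hashed iteratively to radius 3 with
charge-insensitive invariants (element, degree, bond-order sum, ring
membership), and identifiers are folded to 2048 presence bits. Full
charge-normalization chemistry (protonation-state canonicalization) is
out of scope of this standardization; the invariants are simply
charge-blind. Proteins: per aligned position the residue's three Hellberg
z-scale values, gaps and unknown codes contributing (0, 0, 0), giving a
`3 × alignment-length` block; the alignment is consumed as input, not
computed. Assay blocks: any descriptor family, joined per row via its
context id — at inference the caller supplies compound, protein and assay
context together.

**Filters and splits.** On training rows only: drop columns with variance
< 0.05, then walk the survivors in column order and drop any column with
|Pearson r| > 0.8 against an earlier kept column (the later column loses —
an explicit, deterministic tie rule). The resulting mask is applied to
both sides of the split. Splits are 90/10 random, or Bemis–Murcko scaffold
splits in which whole scaffold groups (scaffold = iteratively pruned
molecular graph, ring systems plus linkers, canonicalized by invariant
hashing) are assigned to the test side in seeded order by a greedy
subset-sum that lands the realized test fraction as close to the target as
the group granularity allows; no scaffold ever appears on both sides.

**Boosting.** Gradient-boosted regression trees (xgboost backend behind a
spec contract): at most 1000 trees, learning rate 0.1, minimum 50 data
points per leaf, depth 8, 80% row subsampling, squared-error loss, early
stopping on the R² of a seeded 10% holdout carved from the training rows
(patience 20 rounds). The realized tree count is recorded on the model.

**Masked multitask.** One output per assay cluster. The model is trained
on the stacked (row, observed-task) representation with a one-hot task
block appended to the features. This optimizes *exactly* the squared error
summed over observed target-matrix entries: masked entries are absent from
the stack, so they contribute zero loss and zero gradient (the tests
verify that perturbing masked entries leaves the fit bit-identical). With
a single fully observed task the stack equals the single-task design — the
constant indicator block is dropped — so the multitask trainer reduces
exactly to the single-task trainer. Relative to one-tree-per-output
multioutput boosting this formulation shares all tree structure across
tasks and conditions on the task through splits, which is the same
statistical coupling that makes multitask transfer possible.

**Metrics.** R², RMSE, and Kendall's Tau — the tie-corrected tau-b, since
aggregated pChEMBL values tie frequently. Multitask models report per-task
metrics over observed test entries plus a task-size-weighted average;
tasks with fewer than two observed test points are excluded and logged.
Feature importance is the per-feature cumulative split gain (squared-error
reduction, the additive bookkeeping of the loss actually optimized),
summarized as block proportions (molecule / protein / assay) over the top
30 features.

## Synthetic data

`generate_assay_corpus()` emulates what distinguishes real assay families:
archetype-private keyword vocabulary (radioligand displacement, cAMP
accumulation, calcium flux, enzyme inhibition, transporter uptake), shared
filler vocabulary, and archetype-correlated metadata. Descriptions are
8–20 tokens, ~60% archetype keywords and ~40% filler. Disjoint keyword
pools are enforced so archetypes are separable with a known margin by any
lexical-overlap-preserving embedding — that is what makes recovery
experiments interpretable. `generate_bioactivity()` draws
`pchembl = μ_t + β_c + δ_archetype + ε` with `μ_t ~ N(6.5, 0.5²)`,
`β_c ~ N(0, 1)`, `δ ~ N(0, offset_sd²)` once per archetype, and
`ε ~ N(0, noise_sd²)`; each pair is measured in `Poisson(rate) + 1` assays
with uniformly sampled archetypes. Compounds carry valid drug-like SMILES
from a packaged 577-structure list spanning 45 scaffolds; proteins are
mutated copies of a random consensus (pre-aligned, no gaps).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: paraphrase variation without lexical overlap,
correlated or non-additive assay effects, censored values, heteroscedastic
noise, class-imbalanced archetypes, and structure–activity relationships
(the compound effect is a random intercept, so models generalize to unseen
compounds only through shared substructures of the molecular graph, not
through a planted structure–activity rule).

## Numerical choices and degenerate inputs

* Description length is counted in Unicode characters after trimming
  surrounding whitespace; "more than 500 characters" and "more than 100
  unique compounds" are strict inequalities (boundary values retained and
  removed, respectively).
* The compound-count filter is target-level and applied after all
  row-level filters; row-level filters commute (asserted).
* Deduplication of descriptions uses exact string equality after trimming.
* An all-outlier clustering is a valid result (warning, labels −1);
  degenerate label sets (modal prevalence 1) are an error for normalized
  purity; AMI with a vanishing denominator is defined as 0 with a warning.
* All seeded stages restore the caller's RNG state; reruns are
  byte-identical.
* Test problem sizes were chosen as the smallest at which each property is
  stable: 5 archetypes × 200 descriptions for recovery, 10 targets × 50
  compounds for the variance decomposition, 10 × 100 with archetype-offset
  sd 0.7 for the model comparison.

## Known limitations

* The linear reducer needs clearer lexical separation than a manifold
  reducer would; very small corpora (below ~5× the minimum cluster size
  per topic) tend to come back as outliers.
* The hash-projection embedder cannot represent semantic similarity
  without shared tokens; conclusions about pretrained-embedding quality do
  not transfer from it.
* Scaffold keys are invariant-hash canonicalizations of the pruned
  molecular graph: collisions are astronomically unlikely but not
  impossible, and element-blind graph symmetries are not re-checked.
* The allosteric-modulator exclusion applied in some curated datasets is
  supported only as a user-supplied document exclusion list; it is not
  reproducible from first principles.
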