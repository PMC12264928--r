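# Molecular featurization. SMILES parsing is delegated to
# ChemmineR/ChemmineOB; on the resulting molecular graph this file computes
# an ECFP6-style circular fingerprint (Morgan neighborhood hashing, radius 3,
# folded to a fixed bit length) and a Bemis-Murcko scaffold key (iterative
# pruning of acyclic terminal atoms, leaving ring systems plus linkers).
# Standardization before fingerprinting keeps the largest connected fragment
# (salt stripping) and uses charge-insensitive atom invariants.

# Parse unique SMILES into molecular graphs: list(elements, bonds) or NULL
# for unparsable input.
.parse_smiles <- function(smiles) {
  uniq <- unique(smiles)
  graphs <- stats::setNames(vector("list", length(uniq)), uniq)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(uniq, uniq))),
    error = function(e) NULL)
  one_graph <- function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(ab) || nrow(ab) == 0L) return(NULL)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- if (is.null(bb) || nrow(bb) == 0L)
      matrix(integer(0), ncol = 3L)
    else cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]),
               as.integer(bb[, 3L]))
    list(elements = elements, bonds = bonds)
  }
  if (!is.null(sdfset)) {
    ok <- ChemmineR::validSDF(sdfset)
    ids <- ChemmineR::sdfid(sdfset)
    for (i in which(ok)) {
      g <- tryCatch(one_graph(sdfset[[i]]), error = function(e) NULL)
      graphs[[ids[i]]] <- g
    }
  } else {
    for (s in uniq) {
      g <- tryCatch({
        one <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, s)))
        if (ChemmineR::validSDF(one)[1L]) one_graph(one[[1L]]) else NULL
      }, error = function(e) NULL)
      graphs[[s]] <- g
    }
  }
  graphs[smiles]
}

# salt stripping: largest connected component of the molecular graph
.largest_fragment <- function(g) {
  n <- length(g$elements)
  if (n <= 1L || nrow(g$bonds) == 0L) {
    if (n > 1L) {  # disconnected atoms, no bonds: keep first atom
      return(list(elements = g$elements[1L],
                  bonds = matrix(integer(0), ncol = 3L)))
    }
    return(g)
  }
  ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE],
                                    directed = FALSE)
  if (igraph::vcount(ig) < n)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  comp <- igraph::components(ig)
  if (comp$no == 1L) return(g)
  big <- which.max(comp$csize)
  keep <- which(comp$membership == big)
  remap <- match(seq_len(n), keep)
  bsel <- g$bonds[, 1L] %in% keep & g$bonds[, 2L] %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  bonds[, 1L] <- remap[bonds[, 1L]]
  bonds[, 2L] <- remap[bonds[, 2L]]
  list(elements = g$elements[keep], bonds = bonds)
}

# per-atom ring membership: an atom is in a ring iff one of its edges lies
# on a cycle (i.e. is not a bridge)
.ring_atoms <- function(g) {
  n <- length(g$elements)
  in_ring <- rep(FALSE, n)
  if (nrow(g$bonds) == 0L) return(in_ring)
  ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE],
                                    directed = FALSE)
  if (igraph::vcount(ig) < n)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  br <- igraph::bridges(ig)
  cyc_edges <- setdiff(seq_len(nrow(g$bonds)), as.integer(br))
  if (length(cyc_edges)) {
    in_ring[unique(as.vector(g$bonds[cyc_edges, 1:2]))] <- TRUE
  }
  in_ring
}

# Morgan-style iterative neighborhood invariants; returns all invariants
# generated at radii 0..radius (the identifier multiset of the molecule)
.morgan_invariants <- function(g, radius = 3L) {
  n <- length(g$elements)
  nbrs <- vector("list", n)
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1L]; j <- g$bonds[b, 2L]; o <- g$bonds[b, 3L]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  in_ring <- .ring_atoms(g)
  elem_code <- vapply(g$elements, .hash_string, numeric(1))
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  bond_sum <- vapply(nbrs, function(x) if (is.null(x)) 0L
                     else sum(x[, 2L]), numeric(1))
  inv <- vapply(seq_len(n), function(i)
    .hash_ints(c(elem_code[i], degree[i], bond_sum[i],
                 as.integer(in_ring[i]))), numeric(1))
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb)) return(.hash_ints(c(r, inv[i])))
      pairs <- cbind(nb[, 2L], inv[nb[, 1L]])
      ord <- order(pairs[, 1L], pairs[, 2L])
      .hash_ints(c(r, inv[i], as.vector(t(pairs[ord, , drop = FALSE]))))
    }, numeric(1))
    inv <- inv_new
    all_inv <- c(all_inv, inv)
  }
  all_inv
}

#' Circular fingerprints of molecules
#'
#' ECFP6-style extended-connectivity fingerprints: each SMILES is parsed,
#' standardized (largest fragment kept), atom neighborhoods are hashed
#' iteratively out to the given radius (3 bonds, i.e. diameter 6), and the
#' resulting substructure identifiers are folded into a fixed-length binary
#' vector. Deterministic: identical SMILES always give identical bits.
#'
#' @param smiles Character vector of SMILES.
#' @param n_bits Folded length (default 2048).
#' @param radius Neighborhood radius in bonds (default 3).
#' @return Binary matrix `length(smiles) x n_bits` with column names
#'   `fp_1..fp_n`. Unparsable SMILES give all-`NA` rows and are listed in the
#'   `"errors"` attribute.
#' @export
featurize_molecules <- function(smiles, n_bits = 2048L, radius = 3L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  graphs <- .parse_smiles(smiles)
  out <- matrix(NA_real_, nrow = length(smiles), ncol = n_bits,
                dimnames = list(NULL, paste0("fp_", seq_len(n_bits))))
  uniq <- unique(smiles)
  rows <- stats::setNames(vector("list", length(uniq)), uniq)
  for (s in uniq) {
    g <- graphs[[s]]
    if (is.null(g)) next
    g <- .largest_fragment(g)
    inv <- .morgan_invariants(g, radius)
    v <- numeric(n_bits)
    v[(inv %% n_bits) + 1L] <- 1
    rows[[s]] <- v
  }
  for (i in seq_along(smiles)) {
    if (!is.null(rows[[smiles[i]]])) out[i, ] <- rows[[smiles[i]]]
  }
  bad <- vapply(seq_along(smiles), function(i) is.null(rows[[smiles[i]]]),
                logical(1))
  attr(out, "errors") <- smiles[bad]
  out
}

#' Bemis-Murcko scaffold keys
#'
#' Computes, per molecule, a canonical key for its Bemis-Murcko scaffold:
#' the graph obtained by iteratively pruning terminal (degree-one) atoms,
#' which leaves the ring systems plus the linkers connecting them. The key
#' is a hash of the sorted Morgan invariant multiset of that scaffold graph,
#' so two molecules share a key exactly when their scaffold graphs hash
#' identically. Acyclic molecules share the key `"acyclic"`; unparsable
#' SMILES give `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of scaffold keys.
#' @export
murcko_scaffolds <- function(smiles) {
  graphs <- .parse_smiles(smiles)
  uniq <- unique(smiles)
  keys <- stats::setNames(rep(NA_character_, length(uniq)), uniq)
  for (s in uniq) {
    g <- graphs[[s]]
    if (is.null(g)) next
    g <- .largest_fragment(g)
    if (!any(.ring_atoms(g))) {
      keys[s] <- "acyclic"
      next
    }
    repeat {
      n <- length(g$elements)
      deg <- integer(n)
      if (nrow(g$bonds)) {
        t1 <- table(factor(g$bonds[, 1L], levels = seq_len(n)))
        t2 <- table(factor(g$bonds[, 2L], levels = seq_len(n)))
        deg <- as.integer(t1) + as.integer(t2)
      }
      drop <- which(deg <= 1L)
      if (length(drop) == 0L || length(drop) == n) break
      keep <- setdiff(seq_len(n), drop)
      remap <- match(seq_len(n), keep)
      bsel <- g$bonds[, 1L] %in% keep & g$bonds[, 2L] %in% keep
      bonds <- g$bonds[bsel, , drop = FALSE]
      bonds[, 1L] <- remap[bonds[, 1L]]
      bonds[, 2L] <- remap[bonds[, 2L]]
      g <- list(elements = g$elements[keep], bonds = bonds)
    }
    if (nrow(g$bonds) == 0L) {
      keys[s] <- "acyclic"
    } else {
      inv <- .morgan_invariants(g, radius = 2L)
      keys[s] <- sprintf("scaffold_%.0f", .hash_ints(sort(inv)))
    }
  }
  unname(keys[smiles])
}
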