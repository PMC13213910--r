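#' Circular (Morgan-style) fingerprints for diversity analysis
#'
#' Hashes each heavy atom's circular environment out to the given radius
#' (radius 2 corresponds to ECFP4-class fingerprints) and folds the
#' resulting identifiers into a fixed-length bit vector.  The initial
#' atom invariant combines element, degree, maximum bond order and ring
#' membership; each iteration mixes an atom's invariant with the sorted
#' (bond order, neighbour invariant) pairs of its neighbours.
#'
#' @param smiles Character vector of SMILES, optionally named by ligand
#'   id.
#' @param ids Ligand ids (defaults to names of `smiles`).
#' @param radius Neighbourhood radius (default 2).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return Integer 0/1 matrix, one row per molecule, with ligand ids as
#'   row names.
#' @export
morgan_fingerprints <- function(smiles, ids = NULL, radius = 2,
                                n_bits = 2048) {
  sdfset <- parse_smiles(smiles, ids)
  fp <- matrix(0L, nrow = length(sdfset), ncol = n_bits,
               dimnames = list(ChemmineR::cid(sdfset), NULL))
  for (i in seq_along(sdfset)) {
    mg <- mol_graph(sdfset[[i]])
    fp[i, circular_bits(mg, radius, n_bits)] <- 1L
  }
  fp
}

## deterministic integer mixing kept below 2^31 (FNV-style)
hash_ints <- function(v) {
  h <- 2166136261 %% 2147483647
  for (x in v) h <- (h * 16777619 + x + 1) %% 2147483647
  h
}

circular_bits <- function(mg, radius, n_bits) {
  n <- length(mg$elements)
  if (n == 0L) return(integer(0))
  elem_code <- match(mg$elements,
                     c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                       "B", "Si", "Se", "H"), nomatch = 99L)
  nbrs <- lapply(seq_len(n), function(i) integer(0))
  bond_ord <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(mg$bonds))) {
    f <- mg$bonds$from[b]; t <- mg$bonds$to[b]; o <- mg$bonds$order[b]
    nbrs[[f]] <- c(nbrs[[f]], t); bond_ord[[f]] <- c(bond_ord[[f]], o)
    nbrs[[t]] <- c(nbrs[[t]], f); bond_ord[[t]] <- c(bond_ord[[t]], o)
  }
  inv <- vapply(seq_len(n), function(i)
    hash_ints(c(elem_code[i], length(nbrs[[i]]),
                sum(bond_ord[[i]]), as.integer(mg$ring_atom[i]))),
    numeric(1))
  all_ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      pairs <- cbind(bond_ord[[i]], inv[nbrs[[i]]])
      if (nrow(pairs))
        pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
      hash_ints(c(r, inv[i], t(pairs)))
    }, numeric(1))
    all_ids <- c(all_ids, inv)
  }
  unique(as.integer(all_ids %% n_bits) + 1L)
}

#' Pairwise Tanimoto similarity of bit fingerprints
#'
#' @param fp 0/1 fingerprint matrix (rows = molecules), as from
#'   [morgan_fingerprints()].
#' @return Symmetric similarity matrix with unit diagonal.  Two empty
#'   fingerprints are given similarity 1 (indistinguishable), an empty
#'   versus non-empty pair 0.
#' @export
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp) * 1
  common <- tcrossprod(fp)
  on_bits <- diag(common)
  denom <- outer(on_bits, on_bits, `+`) - common
  sim <- ifelse(denom > 0, common / denom, 1)
  diag(sim) <- 1
  sim
}
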