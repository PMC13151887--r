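#' @name fingerprints
#' @title Circular fingerprints and Tanimoto similarity
#'
#' @description
#' 2048-bit circular (Morgan-style) fingerprints of radius 2 computed on the
#' heavy-atom graph.  The initial atom invariant combines element, degree,
#' total bond order and ring membership; each expansion round hashes the
#' sorted (bond order, neighbour identifier) list into a new identifier.
#' All identifiers over all radii set one bit each (modulo 2048).  The bit
#' width and radius are package constants chosen to mirror the common ECFP4
#' configuration.
NULL

FP_BITS <- 2048L
FP_RADIUS <- 2L

# deterministic polynomial string hash modulo 2^31 - 1
hash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  h
}

#' Circular fingerprint of a molecule
#'
#' @param mol A [molecule_graph()] (or SMILES string).
#' @param nbits Number of bits (default 2048).
#' @param radius Neighbourhood radius (default 2).
#' @return Logical vector of length `nbits`.
#' @export
circular_fp <- function(mol, nbits = FP_BITS, radius = FP_RADIUS) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molecule_graph"))
  n <- mol$n
  B <- bond_order_matrix(mol)
  ringat <- ring_atom_flags(mol)
  ids <- vapply(seq_len(n), function(i) {
    hash31(paste(mol$atom_types[i], sum(B[i, ] > 0),
                 round(sum(B[i, ]) * 10), as.integer(ringat[i]), sep = "|"))
  }, numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      nb <- which(B[i, ] > 0)
      if (!length(nb)) return(ids[i])
      pairs <- sprintf("%g:%.0f", B[i, nb] * 10, ids[nb])
      hash31(paste(c(sprintf("%.0f", ids[i]), sort(pairs)), collapse = ","))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- rep(FALSE, nbits)
  bits[(all_ids %% nbits) + 1L] <- TRUE
  bits
}

#' Tanimoto similarity of two bit fingerprints
#'
#' @param a,b Logical fingerprint vectors of equal length.
#' @return Similarity in \[0,1\] (1 for two empty fingerprints).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Build a fingerprint index over a molecule set
#'
#' @param mols List of [molecule_graph()] objects or SMILES character vector.
#' @param nbits,radius Fingerprint parameters.
#' @return Object of class `fp_index`: a logical matrix (one row per
#'   molecule) with the fingerprint parameters attached.
#' @export
fingerprint_index <- function(mols, nbits = FP_BITS, radius = FP_RADIUS) {
  if (is.character(mols)) mols <- lapply(mols, parse_smiles)
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  if (!length(mols)) stop("empty molecule set")
  m <- t(vapply(mols, circular_fp, logical(nbits),
                nbits = nbits, radius = radius))
  structure(m, class = "fp_index", nbits = nbits, radius = radius)
}

# max Tanimoto of fingerprint fp against all rows of index (vectorized)
max_tanimoto <- function(fp, index) {
  idx <- unclass(index)
  inter <- as.numeric(idx %*% fp)
  uni <- rowSums(idx) + sum(fp) - inter
  sims <- ifelse(uni == 0, 1, inter / uni)
  max(sims)
}

# full pairwise Tanimoto matrix for a fingerprint matrix (rows = molecules)
tanimoto_matrix <- function(fpm) {
  fpm <- unclass(fpm) * 1
  inter <- fpm %*% t(fpm)
  pop <- rowSums(fpm)
  uni <- outer(pop, pop, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  s
}
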