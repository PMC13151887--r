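#' @importFrom stats rnorm runif setNames cor ks.test sd var chisq.test
#' @importFrom utils head tail
NULL

MOL_ELEMENTS <- c("C", "N", "O", "F", "S", "Cl")

# 2005 IUPAC masses (matching the OpenBabel table, so the surrogate and the
# toolkit property backends agree on molecular weight)
ATOMIC_MASS <- c(C = 12.0107, N = 14.0067, O = 15.9994, F = 18.9984032,
                 S = 32.065, Cl = 35.453, H = 1.00794)

#' Valence table and bond-distance threshold
#'
#' Maximum heavy-atom valences for the six-element alphabet
#' \{C, N, O, F, S, Cl\} together with the bond-distance threshold
#' \eqn{\tau_{bond}} (default 1.8 Angstrom) used by the bond-consistency loss
#' and by distance-based bond inference.  Sulfur defaults to divalent and can
#' be raised to 6 for hypervalent chemistry.
#'
#' @param sulfur_vmax Maximum valence for S (2 or 6).
#' @param bond_threshold Bond distance threshold in Angstrom.
#' @return An object of class `valence_table`.
#' @examples
#' vt <- valence_table()
#' max_valence("C", vt)  # 4
#' @export
valence_table <- function(sulfur_vmax = 2L, bond_threshold = 1.8) {
  stopifnot(sulfur_vmax %in% c(2L, 6L), bond_threshold > 0)
  structure(list(
    vmax = c(C = 4L, N = 3L, O = 2L, F = 1L, S = as.integer(sulfur_vmax),
             Cl = 1L),
    bond_threshold = bond_threshold
  ), class = "valence_table")
}

#' Maximum valence of an atom type
#'
#' @param atom_type Element symbol, one of C, N, O, F, S, Cl.
#' @param table A [valence_table()].
#' @return Integer maximum valence.
#' @export
max_valence <- function(atom_type, table = valence_table()) {
  stopifnot(inherits(table, "valence_table"))
  if (length(atom_type) != 1L || !atom_type %in% names(table$vmax)) {
    stop("unknown element '", atom_type, "'; expected one of ",
         paste(names(table$vmax), collapse = ", "))
  }
  unname(table$vmax[[atom_type]])
}

#' Construct a molecular graph
#'
#' The central container of the package: `n` heavy atoms with Cartesian 3D
#' coordinates (Angstrom), atom types over \{C, N, O, F, S, Cl\}, an explicit
#' bond list with orders (1, 2, 3, or 1.5 for aromatic), and optionally a
#' predicted bond-probability matrix (the denoiser output).  Hydrogens are
#' implicit: each heavy atom carries enough implicit H to fill its valence.
#' Coordinates are centred at the centre of mass on construction, which makes
#' translation invariance of the denoiser hold trivially.
#'
#' @param atom_types Character vector of element symbols.
#' @param coords n x 3 numeric matrix of positions in Angstrom.
#' @param bonds Data frame with columns `i`, `j`, `order`, or NULL.
#' @param bond_probs Optional n x n symmetric matrix in \[0,1\], zero diagonal.
#' @param center Centre coordinates at zero mean (default TRUE).
#' @param name Optional molecule name.
#' @return Object of class `molecule_graph`.
#' @export
molecule_graph <- function(atom_types, coords, bonds = NULL, bond_probs = NULL,
                           center = TRUE, name = NULL) {
  atom_types <- as.character(atom_types)
  n <- length(atom_types)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix")
  }
  bad <- which(!stats::complete.cases(coords) | !is.finite(rowSums(coords)))
  if (length(bad)) {
    stop("missing or non-finite coordinates for atom index ", bad[1L])
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
  if (nrow(bonds)) {
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    stopifnot(all(bonds$i >= 1L), all(bonds$j <= n), all(bonds$i != bonds$j),
              all(bonds$order %in% c(1, 1.5, 2, 3)))
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
  }
  if (center && n > 0L) coords <- sweep(coords, 2L, colMeans(coords))
  if (!is.null(bond_probs)) {
    bond_probs <- as.matrix(bond_probs)
    stopifnot(nrow(bond_probs) == n, ncol(bond_probs) == n,
              all(bond_probs >= 0), all(bond_probs <= 1))
    bond_probs <- (bond_probs + t(bond_probs)) / 2
    diag(bond_probs) <- 0
  }
  structure(list(n = n, atom_types = atom_types, coords = coords,
                 bonds = bonds, bond_probs = bond_probs, name = name),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph> ", x$n, " atoms (",
      paste(x$atom_types, collapse = ""), "), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# dense bond-order matrix (aromatic = 1.5)
bond_order_matrix <- function(mol) {
  B <- matrix(0, mol$n, mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      B[mol$bonds$i[k], mol$bonds$j[k]] <- mol$bonds$order[k]
      B[mol$bonds$j[k], mol$bonds$i[k]] <- mol$bonds$order[k]
    }
  }
  B
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(mol$n)))
}

# logical per bond row: is the bond part of a ring (i.e. not a bridge)?
ring_bond_flags <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  flags <- rep(TRUE, igraph::ecount(g))
  flags[as.integer(br)] <- FALSE
  flags
}

ring_atom_flags <- function(mol) {
  flags <- rep(FALSE, mol$n)
  rb <- ring_bond_flags(mol)
  if (any(rb)) {
    flags[unique(c(mol$bonds$i[rb], mol$bonds$j[rb]))] <- TRUE
  }
  flags
}

# Smallest ring through each ring bond (list of atom index vectors, one per
# bond; NULL for acyclic bonds).  Shortest path between the endpoints in the
# graph with that edge deleted.
smallest_rings <- function(mol) {
  rb <- ring_bond_flags(mol)
  g <- mol_igraph(mol)
  out <- vector("list", nrow(mol$bonds))
  for (k in which(rb)) {
    g2 <- igraph::delete_edges(g, k)
    sp <- igraph::shortest_paths(g2, from = mol$bonds$i[k],
                                 to = mol$bonds$j[k])$vpath[[1L]]
    if (length(sp)) out[[k]] <- as.integer(igraph::as_ids(sp))
  }
  out
}

# Aromatic perception (simplified Hueckel-style rule, documented in the
# methods vignette): a 5- or 6-membered smallest ring is aromatic when every
# ring atom either participates in a double/aromatic bond or is a heteroatom
# from {N, O, S}.  Bonds entered with order 1.5 are aromatic by declaration.
aromatic_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  arom <- mol$bonds$order == 1.5
  B <- bond_order_matrix(mol)
  sp2 <- vapply(seq_len(mol$n), function(i) any(B[i, ] >= 1.5), logical(1))
  rings <- smallest_rings(mol)
  for (k in seq_len(nb)) {
    ring <- rings[[k]]
    if (is.null(ring) || !(length(ring) %in% c(5L, 6L))) next
    ok <- all(sp2[ring] | mol$atom_types[ring] %in% c("N", "O", "S"))
    if (ok) arom[k] <- TRUE
  }
  arom
}

#' Build the n x n x 8 edge-feature tensor
#'
#' Channels: 1-4 bond-type one-hot (single, double, triple, aromatic),
#' 5 interatomic distance in Angstrom (filled for *all* pairs, bonded or not,
#' because the bond-consistency loss needs distances everywhere), 6 mean
#' bond-angle cosine over adjacent bond pairs, 7 conjugation flag, 8 ring
#' membership flag.  Channels 1-4, 7 and 8 are symmetric and zero on the
#' diagonal.
#'
#' @param mol A [molecule_graph()].
#' @return Numeric array of dimension `c(n, n, 8)`.
#' @export
build_edge_features <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  n <- mol$n
  E <- array(0, dim = c(n, n, 8L))
  D <- as.matrix(stats::dist(mol$coords))
  E[, , 5L] <- D
  if (!nrow(mol$bonds)) return(E)
  arom <- aromatic_bond_flags(mol)
  ringb <- ring_bond_flags(mol)
  B <- bond_order_matrix(mol)
  # multiple-bond participation per atom, for the conjugation rule
  multi <- vapply(seq_len(n), function(i) sum(B[i, ] >= 1.5), numeric(1))
  adj <- lapply(seq_len(n), function(i) which(B[i, ] > 0))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    ch <- if (arom[k]) 4L else match(o, c(1, 2, 3))
    if (is.na(ch)) ch <- 4L
    E[i, j, ch] <- E[j, i, ch] <- 1
    # mean cosine of angles this bond forms with adjacent bonds at both ends
    cosines <- c()
    for (end in list(c(i, j), c(j, i))) {
      a <- end[1L]; b <- end[2L]
      for (kk in setdiff(adj[[a]], b)) {
        v1 <- mol$coords[b, ] - mol$coords[a, ]
        v2 <- mol$coords[kk, ] - mol$coords[a, ]
        den <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
        if (den > 0) cosines <- c(cosines, sum(v1 * v2) / den)
      }
    }
    if (length(cosines)) E[i, j, 6L] <- E[j, i, 6L] <- mean(cosines)
    # conjugation: aromatic, a single bond between two multiply-bonded atoms,
    # or a multiple bond with another multiple bond on either endpoint
    conj <- arom[k] ||
      (o == 1 && multi[i] >= 1 && multi[j] >= 1) ||
      (o >= 2 && (multi[i] >= 2 || multi[j] >= 2))
    if (conj) E[i, j, 7L] <- E[j, i, 7L] <- 1
    if (ringb[k]) E[i, j, 8L] <- E[j, i, 8L] <- 1
  }
  E
}

# heavy-atom bond-order total per atom; aromatic bonds count 1.5 and the
# per-atom sum is rounded (benzene carbon: 1.5 + 1.5 + 1 -> 4)
atom_bond_totals <- function(mol) {
  arom <- aromatic_bond_flags(mol)
  ord <- mol$bonds$order
  ord[arom] <- 1.5
  tot <- numeric(mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      tot[mol$bonds$i[k]] <- tot[mol$bonds$i[k]] + ord[k]
      tot[mol$bonds$j[k]] <- tot[mol$bonds$j[k]] + ord[k]
    }
  }
  round(tot)
}

# implicit hydrogens filling each atom's valence
implicit_h <- function(mol, table = valence_table()) {
  tot <- atom_bond_totals(mol)
  vm <- table$vmax[mol$atom_types]
  vm[is.na(vm)] <- 0L
  pmax(0, vm - tot)
}

#' Check chemical validity of a molecule
#'
#' A molecule is valid when every atom's total heavy-atom bond order does not
#' exceed the maximum valence for its element and all elements belong to the
#' supported alphabet.  Character input is parsed as SMILES first; a parse
#' failure yields `valid = FALSE` with an `"unparseable"` violation rather
#' than an error.
#'
#' @param x A [molecule_graph()] or a single SMILES string.
#' @param table A [valence_table()].
#' @return List with `valid` (logical) and `violations` (character vector
#'   naming the atom index and rule for each violation).
#' @export
check_validity <- function(x, table = valence_table()) {
  if (is.character(x)) {
    mol <- tryCatch(parse_smiles(x), error = function(e) NULL)
    if (is.null(mol)) {
      return(list(valid = FALSE, violations = "unparseable"))
    }
    x <- mol
  }
  stopifnot(inherits(x, "molecule_graph"))
  viol <- character()
  unknown <- which(!x$atom_types %in% names(table$vmax))
  for (i in unknown) {
    viol <- c(viol, sprintf("element %s unsupported (atom %d)",
                            x$atom_types[i], i))
  }
  tot <- atom_bond_totals(x)
  for (i in setdiff(seq_len(x$n), unknown)) {
    vm <- table$vmax[[x$atom_types[i]]]
    if (tot[i] > vm) {
      viol <- c(viol, sprintf("valence %s %g>%d (atom %d)",
                              x$atom_types[i], tot[i], vm, i))
    }
  }
  list(valid = length(viol) == 0L, violations = viol)
}
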