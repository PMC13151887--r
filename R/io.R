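#' @name io
#' @title Molecule file I/O
#'
#' @description
#' Readers and writers for SMILES line files (one record per line, optional
#' tab-separated name), SDF V2000 and XYZ.  Parsing and canonicalization of
#' SMILES/SDF go through OpenBabel via ChemmineR/ChemmineOB; XYZ files carry
#' no bond block, so bonds are inferred from the interatomic distance
#' threshold of the [valence_table()].  All readers tolerate malformed
#' records: bad entries are skipped, counted in the `skipped` attribute of
#' the result, and reported with a message.
NULL

strip_ob_line <- function(s) {
  s <- sub("[\t ].*$", "", trimws(s))
  s
}

# canonicalize one SMILES with OpenBabel, dropping stereo annotations
# (stereochemistry assignment is out of scope for this package)
ob_canon <- function(smi) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smi)),
    error = function(e) "")
  out <- strip_ob_line(out)
  if (!nzchar(out)) return(NA_character_)
  plain <- gsub("[@/\\\\]", "", out)
  if (!identical(plain, out)) {
    out <- strip_ob_line(tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", plain)),
      error = function(e) ""))
    if (!nzchar(out)) return(NA_character_)
  }
  out
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` for unparseable input.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, ob_canon, character(1), USE.NAMES = FALSE)
}

# SDFset single molecule -> molecule_graph (NULL on failure)
sdf_to_graph <- function(sdf, name = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  el <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  bonds <- if (!is.null(bb) && nrow(bb) > 0L) {
    ord <- as.numeric(bb[, 3L])
    ord[ord == 4] <- 1.5  # SDF aromatic code
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = ord)
  } else NULL
  molecule_graph(el, coords, bonds, name = name)
}

#' Parse a SMILES string into a molecule graph
#'
#' OpenBabel converts the SMILES to an SDF block (2D coordinates) which is
#' then lifted into a [molecule_graph()].  Kekulized aromatic rings are
#' re-perceived internally.  Errors on unparseable input; use
#' [check_validity()] for a non-throwing path.
#'
#' @param smiles A single SMILES string.
#' @param name Optional molecule name.
#' @return A [molecule_graph()].
#' @export
parse_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdftxt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) "")
  if (!nzchar(sdftxt) || !grepl("V2000", sdftxt, fixed = TRUE)) {
    stop("unparseable SMILES: ", smiles)
  }
  sdfset <- methods::as(ChemmineR::read.SDFstr(textConnection(sdftxt)), "SDFset")
  g <- sdf_to_graph(sdfset[[1L]], name = name)
  if (is.null(g)) stop("unparseable SMILES: ", smiles)
  g
}

# molecule_graph -> V2000 SDF text (aromatic written as bond code 4)
graph_to_sdf_text <- function(mol, name = NULL) {
  nm <- if (!is.null(name)) name else if (!is.null(mol$name)) mol$name else "mol"
  nb <- nrow(mol$bonds)
  lines <- c(nm, " moldiffrl", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", mol$n, nb))
  for (i in seq_len(mol$n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              mol$coords[i, 1L], mol$coords[i, 2L],
                              mol$coords[i, 3L], mol$atom_types[i]))
  }
  arom <- aromatic_bond_flags(mol)
  for (k in seq_len(nb)) {
    code <- if (isTRUE(arom[k])) 4L else as.integer(round(mol$bonds$order[k]))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$i[k], mol$bonds$j[k], code))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical SMILES of a molecule graph
#'
#' @param mol A [molecule_graph()].
#' @return Canonical SMILES string (`NA` if conversion fails).
#' @export
graph_to_smiles <- function(mol) {
  txt <- graph_to_sdf_text(mol)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt)),
    error = function(e) "")
  out <- strip_ob_line(out)
  if (!nzchar(out)) return(NA_character_)
  plain <- gsub("[@/\\\\]", "", out)
  if (!identical(plain, out)) return(ob_canon(plain))
  out
}

parse_xyz_text <- function(lines) {
  mols <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L || i + 1L + n > length(lines) + 0L) {
      stop("malformed XYZ record at line ", i)
    }
    name <- trimws(lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    el <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    mols[[length(mols) + 1L]] <- list(el = el, coords = xyz,
                                      name = if (nzchar(name)) name else NULL)
    i <- i + 2L + n
  }
  mols
}

# infer single bonds from the distance threshold (XYZ carries no bond block)
xyz_to_graph <- function(el, coords, name = NULL, table = valence_table()) {
  n <- length(el)
  D <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(D) & D < table$bond_threshold, arr.ind = TRUE)
  bonds <- if (nrow(idx)) {
    data.frame(i = idx[, 1L], j = idx[, 2L], order = 1)
  } else NULL
  molecule_graph(el, coords, bonds, center = FALSE, name = name)
}

#' Read molecules from a file
#'
#' @param path File path.
#' @param format One of `"smiles"`, `"sdf"`, `"xyz"`.
#' @param table A [valence_table()] (used for XYZ bond inference).
#' @return List of [molecule_graph()] objects with attribute `skipped`
#'   counting malformed records.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf", "xyz"),
                           table = valence_table()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  skipped <- 0L
  mols <- list()
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(ln, "\t")[[1L]]
      smi <- trimws(parts[1L])
      nm <- if (length(parts) > 1L) trimws(parts[2L]) else NULL
      g <- tryCatch(parse_smiles(smi, name = nm), error = function(e) NULL)
      if (is.null(g)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- g
    }
  } else if (format == "sdf") {
    sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                       error = function(e) stop("cannot read SDF: ", path))
    for (k in seq_along(sdfset)) {
      g <- tryCatch(
        sdf_to_graph(sdfset[[k]],
                     name = tryCatch(ChemmineR::sdfid(sdfset[k]),
                                     error = function(e) NULL)),
        error = function(e) NULL)
      if (is.null(g)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- g
    }
  } else {
    recs <- parse_xyz_text(readLines(path, warn = FALSE))
    for (r in recs) {
      g <- tryCatch(xyz_to_graph(r$el, r$coords, r$name, table),
                    error = function(e) NULL)
      if (is.null(g)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- g
    }
  }
  if (skipped > 0L) message(skipped, " malformed record(s) skipped in ", path)
  attr(mols, "skipped") <- skipped
  mols
}

#' Write molecules to a file
#'
#' @param mols List of [molecule_graph()] objects.
#' @param path Output path.
#' @param format One of `"smiles"`, `"sdf"`, `"xyz"`.
#' @return Invisibly, the path.
#' @export
write_molecules <- function(mols, path, format = c("smiles", "sdf", "xyz")) {
  format <- match.arg(format)
  if (format == "smiles") {
    smis <- vapply(mols, graph_to_smiles, character(1))
    nm <- vapply(mols, function(m) if (is.null(m$name)) "" else m$name,
                 character(1))
    lines <- ifelse(nzchar(nm), paste(smis, nm, sep = "\t"), smis)
    writeLines(lines[!is.na(smis)], path)
  } else if (format == "sdf") {
    writeLines(vapply(mols, graph_to_sdf_text, character(1)), path)
  } else {
    out <- unlist(lapply(mols, function(m) {
      c(as.character(m$n),
        if (is.null(m$name)) "" else m$name,
        sprintf("%s %.6f %.6f %.6f", m$atom_types,
                m$coords[, 1L], m$coords[, 2L], m$coords[, 3L]))
    }))
    writeLines(out, path)
  }
  invisible(path)
}

# ---- scaffolds and fragments ----------------------------------------------

# Bemis-Murcko style scaffold: iteratively prune terminal atoms, keeping a
# terminal atom only when it is multiply bonded to a ring atom (exocyclic
# =O etc.).  Acyclic molecules yield the empty scaffold token "".
murcko_scaffold_graph <- function(mol) {
  keep <- rep(TRUE, mol$n)
  repeat {
    idx <- which(keep)
    if (!length(idx)) break
    sub <- subset_molecule(mol, idx)
    if (!any(ring_bond_flags(sub))) return(NULL)  # acyclic
    ringat <- ring_atom_flags(sub)
    B <- bond_order_matrix(sub)
    deg <- rowSums(B > 0)
    drop <- which(deg <= 1)
    drop <- drop[vapply(drop, function(v) {
      nb <- which(B[v, ] > 0)
      !(length(nb) == 1L && B[v, nb] >= 2 && ringat[nb])
    }, logical(1))]
    drop <- drop[!ringat[drop]]
    if (!length(drop)) return(sub)
    keep[idx[drop]] <- FALSE
  }
  NULL
}

subset_molecule <- function(mol, idx) {
  idx <- sort(idx)
  map <- match(seq_len(mol$n), idx)
  b <- mol$bonds[mol$bonds$i %in% idx & mol$bonds$j %in% idx, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  molecule_graph(mol$atom_types[idx], mol$coords[idx, , drop = FALSE], b,
                 center = FALSE, name = mol$name)
}

# Fragmentation scheme (documented): cut every acyclic single bond with at
# least one endpoint in a ring; connected components with >= 2 heavy atoms
# become fragments.  Acyclic molecules contribute themselves whole.
fragment_graphs <- function(mol) {
  rb <- ring_bond_flags(mol)
  ringat <- ring_atom_flags(mol)
  cut <- which(!rb & mol$bonds$order == 1 &
                 (ringat[mol$bonds$i] | ringat[mol$bonds$j]))
  b <- mol$bonds[setdiff(seq_len(nrow(mol$bonds)), cut), , drop = FALSE]
  tmp <- molecule_graph(mol$atom_types, mol$coords, b, center = FALSE)
  comp <- igraph::components(mol_igraph(tmp))$membership
  out <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) >= 2L) out[[length(out) + 1L]] <- subset_molecule(tmp, idx)
  }
  out
}

#' Bemis-Murcko scaffolds and fragments of a molecule set
#'
#' Scaffolds are computed by iterative side-chain pruning (ring systems plus
#' linkers, retaining exocyclic multiple bonds); acyclic molecules map to the
#' empty token `""` and are counted separately.  Fragments come from cutting
#' every acyclic single bond adjacent to a ring atom and collecting connected
#' components with at least two heavy atoms.
#'
#' @param mols List of [molecule_graph()] objects.
#' @return List with `scaffolds` (character vector, one canonical SMILES per
#'   molecule, `""` for acyclic), `fragments` (character set of canonical
#'   fragment SMILES), and `n_acyclic`.
#' @export
scaffold_and_fragments <- function(mols) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  scaff <- vapply(mols, function(m) {
    sg <- murcko_scaffold_graph(m)
    if (is.null(sg)) "" else {
      s <- graph_to_smiles(sg)
      if (is.na(s)) "" else s
    }
  }, character(1))
  frags <- unique(unlist(lapply(mols, function(m) {
    fs <- vapply(fragment_graphs(m), graph_to_smiles, character(1))
    fs[!is.na(fs)]
  })))
  if (is.null(frags)) frags <- character()
  list(scaffolds = scaff, fragments = sort(frags),
       n_acyclic = sum(scaff == ""))
}
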