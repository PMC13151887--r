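#' @name objectives
#' @title Molecular property scoring and the objective vector
#'
#' @description
#' Computes the per-molecule properties used for conditioning and for the
#' multi-objective reward: QED-style drug-likeness, a synthetic-accessibility
#' score on the 1 (easy) to 10 (hard) scale, logP, molecular weight and the
#' discrete descriptor counts, plus the continuous novelty objective
#' (one minus the maximum Tanimoto similarity to a training-set fingerprint
#' index).  The objective vector is `(QED, -SA, Novelty)` in maximization
#' orientation.
#'
#' Two property backends exist.  The default `"surrogate"` backend is
#' self-contained: exact molecular weight from atomic masses with implicit
#' hydrogens, an additive per-atom logP table, a ring/branch/size proxy for
#' SA and a bounded multiplicative QED proxy.  The `"openbabel"` backend
#' delegates MW, logP, HBD and HBA to OpenBabel descriptors
#' (ChemmineOB) and keeps the surrogate QED/SA (no QED/SA implementation is
#' available there); it is used as a cross-check in the test-suite.
NULL

# additive per-atom logP contributions (coarse Crippen-style table; a proxy,
# documented as such)
LOGP_CONTRIB <- c(C = 0.20, Caro = 0.30, N = -0.60, O = -0.40,
                  F = 0.22, S = 0.45, Cl = 0.65)

discrete_counts <- function(mol) {
  arom <- aromatic_bond_flags(mol)
  rb <- ring_bond_flags(mol)
  g <- mol_igraph(mol)
  # cyclomatic number = number of independent rings
  comp <- igraph::components(g)$no
  ring_count <- nrow(mol$bonds) - mol$n + comp
  # aromatic ring count from smallest rings over aromatic bonds
  rings <- smallest_rings(mol)
  arings <- unique(vapply(which(arom & rb), function(k) {
    paste(sort(rings[[k]]), collapse = "-")
  }, character(1)))
  hs <- implicit_h(mol)
  hbd <- sum(mol$atom_types %in% c("N", "O") & hs >= 1)
  hba <- sum(mol$atom_types %in% c("N", "O"))
  list(ring_count = max(0L, ring_count), aromatic_rings = length(arings),
       hbd = hbd, hba = hba)
}

surrogate_mw <- function(mol) {
  hs <- implicit_h(mol)
  sum(ATOMIC_MASS[mol$atom_types]) + sum(hs) * ATOMIC_MASS[["H"]]
}

surrogate_logp <- function(mol) {
  arom <- aromatic_bond_flags(mol)
  aroat <- rep(FALSE, mol$n)
  if (any(arom)) {
    aroat[unique(c(mol$bonds$i[arom], mol$bonds$j[arom]))] <- TRUE
  }
  contrib <- ifelse(mol$atom_types == "C" & aroat, LOGP_CONTRIB[["Caro"]],
                    LOGP_CONTRIB[mol$atom_types])
  hs <- implicit_h(mol)
  polarH <- sum(hs[mol$atom_types %in% c("N", "O")])
  sum(contrib) - 0.15 * polarH
}

# ring/branch/size proxy for synthetic accessibility, clamped to [1, 10]
surrogate_sa <- function(mol) {
  dc <- discrete_counts(mol)
  B <- bond_order_matrix(mol)
  deg <- rowSums(B > 0)
  branching <- sum(pmax(0, deg - 2))
  hetero <- sum(mol$atom_types != "C")
  sa <- 1 + 0.08 * mol$n + 0.35 * dc$ring_count - 0.15 * dc$aromatic_rings +
    0.18 * branching + 0.12 * hetero
  min(10, max(1, sa))
}

# bounded QED proxy: geometric mean of simple desirability terms
surrogate_qed <- function(mol, mw = NULL, logp = NULL, dc = NULL) {
  if (is.null(mw)) mw <- surrogate_mw(mol)
  if (is.null(logp)) logp <- surrogate_logp(mol)
  if (is.null(dc)) dc <- discrete_counts(mol)
  d_mw <- exp(-((mw - 300) / 150)^2)
  d_logp <- exp(-((logp - 2.5) / 2)^2)
  d_ring <- exp(-((dc$ring_count - 2) / 2)^2)
  d_hbd <- exp(-(pmax(0, dc$hbd - 5) / 2)^2)
  d_hba <- exp(-(pmax(0, dc$hba - 10) / 3)^2)
  q <- (d_mw * d_logp * d_ring * d_hbd * d_hba)^(1 / 5)
  min(1, max(0, q))
}

clamp_int <- function(x, lo, hi, what) {
  if (x < lo || x > hi) {
    warning(sprintf("%s=%d outside [%d,%d]; clamped", what, x, lo, hi))
    x <- min(hi, max(lo, x))
  }
  as.integer(x)
}

#' Score molecular properties
#'
#' @param mol A [molecule_graph()] or SMILES string.
#' @param backend `"surrogate"` (default, self-contained) or `"openbabel"`
#'   (delegates MW/logP/HBD/HBA to OpenBabel descriptors).
#' @return A `property_record` list with fields `qed`, `sa`, `logp`, `mw`,
#'   `hbd`, `hba`, `ring_count`, `aromatic_rings`.
#' @export
score_properties <- function(mol, backend = c("surrogate", "openbabel")) {
  backend <- match.arg(backend)
  if (is.character(mol)) mol <- parse_smiles(mol)
  chk <- check_validity(mol)
  if (!chk$valid) {
    stop("cannot score an invalid molecule: ",
         paste(chk$violations, collapse = "; "))
  }
  dc <- discrete_counts(mol)
  if (backend == "surrogate") {
    mw <- surrogate_mw(mol)
    logp <- surrogate_logp(mol)
    hbd <- dc$hbd; hba <- dc$hba
  } else {
    smi <- graph_to_smiles(mol)
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smi, "m"))
    p <- ChemmineR::propOB(sdf)
    mw <- p$MW[1L]
    logp <- p$logP[1L]
    hbd <- as.integer(p$HBD[1L])
    hba <- as.integer(p$HBA2[1L])
  }
  rec <- list(
    qed = surrogate_qed(mol, mw = surrogate_mw(mol)),
    sa = surrogate_sa(mol),
    logp = logp,
    mw = mw,
    hbd = clamp_int(hbd, 0L, 5L, "hbd"),
    hba = clamp_int(hba, 0L, 10L, "hba"),
    ring_count = clamp_int(dc$ring_count, 0L, 6L, "ring_count"),
    aromatic_rings = clamp_int(dc$aromatic_rings, 0L, 4L, "aromatic_rings"))
  class(rec) <- "property_record"
  rec
}

#' Continuous novelty objective
#'
#' One minus the maximum Tanimoto similarity between the molecule's circular
#' fingerprint and any fingerprint in the training index.  This is the
#' per-molecule objective used in the reward; the batch-level novelty metric
#' (exact canonical-SMILES membership) lives in [distribution_metrics()].
#'
#' @param mol A [molecule_graph()], SMILES string, or logical fingerprint.
#' @param index A [fingerprint_index()] over the training set.
#' @return Novelty in \[0,1\].
#' @export
novelty_score <- function(mol, index) {
  if (!inherits(index, "fp_index") || nrow(index) == 0L) {
    stop("empty or invalid training fingerprint index")
  }
  fp <- if (is.logical(mol)) mol else circular_fp(mol)
  1 - max_tanimoto(fp, index)
}

#' Assemble the maximization-oriented objective vector
#'
#' @param rec A `property_record` (or a list with `qed` and `sa`).
#' @param novelty Novelty value in \[0,1\].
#' @return Numeric vector `(qed, -sa, novelty)`; larger is better in every
#'   slot.
#' @export
objective_vector <- function(rec, novelty) {
  c(qed = rec$qed, neg_sa = -rec$sa, novelty = novelty)
}
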