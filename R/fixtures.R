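#' @name fixtures
#' @title Deterministic desk-scale input generators
#'
#' @description
#' Pure-in-(spec, seed) generators for (i) small valid molecules with
#' idealized 3D geometry, standing in for large drug-like corpora at test
#' scale, (ii) three-objective point clouds with an exactly known Pareto
#' frontier, and (iii) fronts with closed-form hypervolume.  Every generator
#' restores the caller's RNG state.
NULL

# idealized geometry constants (Angstrom / degrees)
BOND_CC <- 1.54
BOND_AROM <- 1.40
ANGLE_TET <- 109.5

# zig-zag backbone positions for a chain of k atoms in the xy-plane
chain_coords <- function(k, bond = BOND_CC) {
  ang <- (180 - ANGLE_TET) / 2 * pi / 180
  pos <- matrix(0, k, 3L)
  for (i in seq_len(k - 1L)) {
    head <- if (i %% 2L == 1L) ang else -ang
    pos[i + 1L, ] <- pos[i, ] + bond * c(cos(head), sin(head), 0)
  }
  pos
}

# planar hexagon
ring6_coords <- function(bond = BOND_AROM) {
  r <- bond / (2 * sin(pi / 6))
  th <- (0:5) * pi / 3
  cbind(r * cos(th), r * sin(th), 0)
}

make_chain_mol <- function(len, jitter) {
  internal <- sample(c("C", "C", "C", "N", "O"), len - 2L, replace = TRUE)
  terminal <- sample(c("C", "C", "N", "O", "F", "Cl", "S"), 2L, replace = TRUE)
  atoms <- c(terminal[1L], internal, terminal[2L])
  coords <- chain_coords(len) +
    matrix(runif(len * 3L, -jitter, jitter), len, 3L)
  bonds <- data.frame(i = seq_len(len - 1L), j = 2:len, order = 1)
  molecule_graph(atoms, coords, bonds)
}

# benzene-like ring (optionally pyridine-type N) with 0-2 substituents
make_ring_mol <- function(jitter, n_sub) {
  atoms <- rep("C", 6L)
  if (runif(1) < 0.4) atoms[1L] <- "N"
  coords <- ring6_coords()
  bonds <- data.frame(i = 1:6, j = c(2:6, 1L),
                      order = rep(c(2, 1), 3L))
  sub_at <- if (n_sub > 0L) sample(2:6, n_sub) else integer()
  for (s in sub_at) {
    el <- sample(c("C", "F", "Cl", "O", "N"), 1L)
    dir <- coords[s, ] / sqrt(sum(coords[s, ]^2))
    coords <- rbind(coords, coords[s, ] + 1.45 * dir)
    atoms <- c(atoms, el)
    bonds <- rbind(bonds, data.frame(i = s, j = length(atoms), order = 1))
  }
  n <- length(atoms)
  coords <- coords + matrix(runif(n * 3L, -jitter, jitter), n, 3L)
  molecule_graph(atoms, coords, bonds)
}

# chain with a mid-chain branch atom
make_branched_mol <- function(len, jitter) {
  m <- make_chain_mol(len, jitter)
  at <- sample(2:(m$n - 1L), 1L)
  if (m$atom_types[at] == "C") {
    el <- sample(c("C", "F", "Cl"), 1L)
    new_pos <- m$coords[at, ] + c(0, 0, 1.45)
    coords <- rbind(m$coords, new_pos)
    atoms <- c(m$atom_types, el)
    bonds <- rbind(m$bonds, data.frame(i = at, j = length(atoms), order = 1))
    return(molecule_graph(atoms, coords, bonds))
  }
  m
}

#' Generate toy molecules with idealized 3D coordinates
#'
#' Valid molecules of 5-15 heavy atoms assembled from valence-respecting
#' templates (zig-zag chains with ether/amine heteroatoms, aromatic
#' six-rings with substituents, branched chains) over the atom alphabet
#' \{C, N, O, F, S, Cl\}, with idealized bond lengths (1.54 A C-C, 1.40 A
#' aromatic) and angles plus seeded coordinate jitter of at most 0.05 A.
#' Every output passes [check_validity()] by construction.
#'
#' @param n Number of molecules.
#' @param seed Integer seed (same `(n, seed)` gives identical output).
#' @param jitter Coordinate jitter amplitude in Angstrom.
#' @return List of [molecule_graph()] objects.
#' @export
gen_toy_molecules <- function(n, seed = 42L, jitter = 0.05) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("chain", "ring", "branched"), 1L,
                     prob = c(0.4, 0.35, 0.25))
      m <- switch(kind,
        chain = make_chain_mol(sample(5:12, 1L), jitter),
        ring = make_ring_mol(jitter, sample(0:2, 1L)),
        branched = make_branched_mol(sample(6:13, 1L), jitter))
      m$name <- sprintf("fix%04d", i)
      m
    })
  })
}

#' Generate an objective cloud with an exactly known Pareto frontier
#'
#' Frontier points are distinct points on the simplex
#' \eqn{x + y + z = c} with positive coordinates: equal coordinate sums make
#' them mutually non-dominating.  Every remaining point is a frontier point
#' scaled by a factor strictly inside (0, 1), hence strictly dominated by
#' its generator.  The rank-1 front of the returned cloud therefore has
#' exactly `n_frontier` points.
#'
#' @param n_total Total number of points.
#' @param n_frontier Number of frontier points (`<= n_total`).
#' @param seed Integer seed.
#' @param total Simplex constant `c` (default 1.5).
#' @return Numeric `n_total x 3` matrix, rows shuffled; attribute
#'   `"frontier"` carries the row indices of the true frontier.
#' @export
gen_objective_cloud <- function(n_total, n_frontier, seed = 42L,
                                total = 1.5) {
  stopifnot(n_frontier >= 1L, n_frontier <= n_total)
  with_seed(seed, {
    F <- matrix(runif(n_frontier * 3L, 0.05, 1), n_frontier, 3L)
    F <- F / rowSums(F) * total
    while (anyDuplicated(round(F, 12L))) {
      dup <- which(duplicated(round(F, 12L)))
      F[dup, ] <- matrix(runif(length(dup) * 3L, 0.05, 1), length(dup))
      F[dup, ] <- F[dup, , drop = FALSE] /
        rowSums(F[dup, , drop = FALSE]) * total
    }
    n_dom <- n_total - n_frontier
    pts <- F
    if (n_dom > 0L) {
      gen <- sample.int(n_frontier, n_dom, replace = TRUE)
      fac <- runif(n_dom, 0.2, 0.95)
      pts <- rbind(F, F[gen, , drop = FALSE] * fac)
    }
    perm <- sample.int(n_total)
    out <- pts[perm, , drop = FALSE]
    attr(out, "frontier") <- match(seq_len(n_frontier), perm)
    out
  })
}

#' Fronts with closed-form hypervolume
#'
#' `kind = "box"`: a single point `(a, b, c)` with hypervolume `a*b*c`
#' against the origin.  `kind = "staircase"`: the symmetric k-step 2D
#' staircase \eqn{p_i = (i/k, (k - i + 1)/k)} with exact hypervolume
#' \eqn{(k + 1)/(2k)}.
#'
#' @param kind `"box"` or `"staircase"`.
#' @param params For `"box"`, list with `a`, `b`, `c`; for `"staircase"`,
#'   list with `k`.
#' @return List with `points` (matrix) and `hv` (exact hypervolume).
#' @export
gen_closed_form_front <- function(kind = c("box", "staircase"),
                                  params = list()) {
  kind <- match.arg(kind)
  if (kind == "box") {
    a <- params$a %||% 1; b <- params$b %||% 1; cc <- params$c %||% 1
    stopifnot(a >= 0, b >= 0, cc >= 0)
    list(points = matrix(c(a, b, cc), 1L), hv = a * b * cc)
  } else {
    k <- params$k %||% 2L
    stopifnot(k >= 1L)
    i <- seq_len(k)
    pts <- cbind(i / k, (k - i + 1) / k)
    list(points = pts, hv = (k + 1) / (2 * k))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
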