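#' Denoiser configuration
#'
#' Architecture of the SE(3)-equivariant message-passing denoiser.  The
#' reference configuration is 12 layers with hidden dimension 256 and
#' cross-attention conditioning at layers \{3, 6, 9, 12\}; tests and smoke
#' training use smaller instances of the same architecture.  Equivariance
#' holds by construction: all node features are built from rotation-invariant
#' quantities (atom types, timestep, interatomic distances) and the predicted
#' coordinate noise is a learned weighted sum of relative position vectors.
#'
#' @param layers Number of message-passing layers.
#' @param hidden Hidden feature dimension.
#' @param cond_layers Layers at which property conditioning is applied
#'   (subset of `1:layers`).
#' @param cond_dim Dimension of the property context rows (matches the
#'   conditioner's model dimension).
#' @param t_dim Sinusoidal timestep-embedding dimension.
#' @param dist_scale Length scale (Angstrom) of the distance-based edge
#'   weights.
#' @param alphabet Atom-type alphabet.
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(layers = 12L, hidden = 256L,
                            cond_layers = c(3L, 6L, 9L, 12L),
                            cond_dim = 256L, t_dim = 64L, dist_scale = 2,
                            alphabet = MOL_ELEMENTS) {
  stopifnot(all(cond_layers >= 1L), all(cond_layers <= layers))
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 cond_layers = as.integer(cond_layers),
                 cond_dim = as.integer(cond_dim), t_dim = as.integer(t_dim),
                 dist_scale = dist_scale, alphabet = alphabet),
            class = "denoiser_config")
}

rmat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(rnorm(nr * nc) * scale, nr, nc)
}

#' Initialize denoiser parameters
#'
#' @param config A [denoiser_config()].
#' @param seed Integer seed controlling the initialization.
#' @return List of parameter matrices with the config attached.
#' @export
init_denoiser <- function(config = denoiser_config(), seed = 1L) {
  with_seed(seed, {
    H <- config$hidden
    na <- length(config$alphabet)
    layers <- lapply(seq_len(config$layers), function(l) {
      list(W1 = rmat(H, H), b1 = matrix(0, 1, H),
           W2a = rmat(H, H), W2b = rmat(H, H), b2 = matrix(0, 1, H))
    })
    cond <- stats::setNames(lapply(config$cond_layers, function(l) {
      list(WQ = rmat(H, H), WK = rmat(config$cond_dim, H),
           WV = rmat(config$cond_dim, H), Wg = rmat(H, H))
    }), as.character(config$cond_layers))
    list(config = config,
         embed = rmat(na, H, 1),
         t_proj = rmat(config$t_dim, H),
         deg_proj = rmat(1, H, 1),
         layers = layers,
         cond = cond,
         coord = list(Wq = rmat(H, H), Wk = rmat(H, H)),
         atom = list(Wa = rmat(H, na), ba = matrix(0, 1, na)),
         bond = list(U = rmat(H, H), a = matrix(0.5, 1, 1),
                     b = matrix(0, 1, 1)))
  })
}

# scalar parameter broadcast to an n x n node: ones %*% a %*% ones^T
ad_bcast_scalar <- function(a, n) {
  tp <- tape_of(a)
  ones_col <- ad_const(tp, matrix(1, n, 1))
  ones_row <- ad_const(tp, matrix(1, 1, n))
  ad_matmul(ad_matmul(ones_col, a), ones_row)
}

# Core forward pass on an AD tape.  `P` is the wrapped parameter structure
# (nodes); coords/atoms are data constants.  Returns nodes.
denoiser_forward_ad <- function(P, config, coords, atoms, t, sched,
                                cond_c = NULL, tape) {
  n <- nrow(coords)
  Xc <- sweep(coords, 2L, colMeans(coords))
  A <- matrix(0, n, length(config$alphabet))
  A[cbind(seq_len(n), match(atoms, config$alphabet))] <- 1
  D2 <- as.matrix(stats::dist(Xc))^2
  Wadj <- exp(-D2 / (2 * config$dist_scale^2))
  diag(Wadj) <- 0
  temb <- matrix(sinusoidal_encode(t, config$t_dim), 1)
  deg <- matrix(rowSums(Wadj), n, 1)

  cA <- ad_const(tape, A)
  cW <- ad_const(tape, Wadj)
  cX <- ad_const(tape, Xc)
  h <- ad_add(ad_add(ad_matmul(cA, P$embed),
                     ad_matmul(ad_const(tape, temb), P$t_proj)),
              ad_matmul(ad_const(tape, deg), P$deg_proj))
  for (l in seq_len(config$layers)) {
    L <- P$layers[[l]]
    msg <- ad_matmul(cW, ad_silu(ad_add(ad_matmul(h, L$W1), L$b1)))
    upd <- ad_silu(ad_add(ad_add(ad_matmul(h, L$W2a),
                                 ad_matmul(msg, L$W2b)), L$b2))
    h <- ad_add(h, upd)
    key <- as.character(l)
    if (!is.null(cond_c) && key %in% names(P$cond)) {
      cw <- P$cond[[key]]
      att <- ad_cross_attend(h, cond_c, cw)
      h <- ad_gated_fuse(h, att, cw$Wg)
    }
  }
  # equivariant coordinate noise: eps_i = sum_j G_ij (x_i - x_j)
  Q <- ad_matmul(h, P$coord$Wq)
  K <- ad_matmul(h, P$coord$Wk)
  G <- ad_emul(ad_scale(ad_matmul(Q, ad_t(K)), 1 / sqrt(config$hidden)), cW)
  rs <- ad_rowsums(G)
  eps <- ad_sub(ad_emul(ad_matmul(rs, ad_const(tape, matrix(1, 1, 3))), cX),
                ad_matmul(G, cX))
  atom_logits <- ad_add(ad_matmul(h, P$atom$Wa), P$atom$ba)
  hu <- ad_matmul(h, P$bond$U)
  S <- ad_scale(ad_matmul(hu, ad_t(hu)), 1 / sqrt(config$hidden))
  geo <- ad_emul(ad_bcast_scalar(P$bond$a, n),
                 ad_const(tape, 1.8 - sqrt(D2)))
  bp <- ad_sigmoid(ad_add(ad_add(S, geo), ad_bcast_scalar(P$bond$b, n)))
  bp <- ad_emul(bp, ad_const(tape, 1 - diag(n)))
  list(eps_coords = eps, atom_logits = atom_logits, bond_probs = bp)
}

#' Denoiser forward pass
#'
#' Predicts the coordinate noise, atom-type logits and bond probabilities for
#' a (possibly corrupted) molecular state at diffusion step `t`.  The
#' coordinate head is SE(3)-equivariant: it rotates with input rotations and
#' ignores translations (inputs are centred); the atom and bond heads are
#' invariant.
#'
#' @param params Parameters from [init_denoiser()].
#' @param coords n x 3 coordinate matrix of the state.
#' @param atoms Character vector of current atom-type assignments.
#' @param t Diffusion timestep.
#' @param sched A [cosine_beta_schedule()].
#' @param cond Optional conditioning context matrix (k x cond_dim), e.g. from
#'   [encode_properties()].
#' @return List with numeric `eps_coords` (n x 3), `atom_logits` (n x
#'   n_types) and `bond_probs` (n x n, symmetric, zero diagonal).
#' @export
denoiser_forward <- function(params, coords, atoms, t, sched, cond = NULL) {
  coords <- as.matrix(coords)
  if (length(atoms) != nrow(coords)) stop("shape mismatch: atoms vs coords")
  tape <- ad_tape()
  wrapped <- ad_wrap_params(tape, params[setdiff(names(params), "config")])
  P <- wrapped$nodes
  cond_c <- if (is.null(cond)) NULL else ad_const(tape, as.matrix(cond))
  out <- denoiser_forward_ad(P, params$config, coords, atoms, t, sched,
                             cond_c = cond_c, tape = tape)
  list(eps_coords = ad_val(out$eps_coords),
       atom_logits = ad_val(out$atom_logits),
       bond_probs = ad_val(out$bond_probs))
}
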