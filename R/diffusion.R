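#' Cosine variance schedule for the diffusion process
#'
#' Builds the squared-cosine cumulative signal schedule
#' \eqn{\bar\alpha_t = f(t)/f(0)}, \eqn{f(t) = \cos^2((t/T + s)/(1 + s)\,
#' \pi/2)} with offset `s = 0.008`, and derives the per-step variances
#' \eqn{\beta_t = 1 - \bar\alpha_t/\bar\alpha_{t-1}}, clipped to the range
#' \[1e-4, 0.02\].  The clipping reconciles the cosine shape with the stated
#' variance range: at the default `T = 1000` the endpoints after clipping are
#' exactly `1e-4` and `0.02`.  The cumulative products are recomputed from
#' the clipped betas, so \eqn{\bar\alpha_0 = 1} and the sequence is strictly
#' decreasing.
#'
#' @param T Number of diffusion steps (default 1000).
#' @param ddim_steps Length of the deterministic sampling sub-schedule
#'   (default 100).
#' @param beta_min,beta_max Clipping range for the per-step variances.
#' @return Object of class `diffusion_schedule` with fields `T`, `betas`,
#'   `alphas`, `alpha_bars` and `ddim_steps`.
#' @export
cosine_beta_schedule <- function(T = 1000L, ddim_steps = 100L,
                                 beta_min = 1e-4, beta_max = 0.02) {
  if (T < 2L) stop("T must be at least 2")
  s <- 0.008
  f <- function(t) cos(((t / T + s) / (1 + s)) * pi / 2)^2
  ab_raw <- f(0:T) / f(0)
  betas <- 1 - ab_raw[-1L] / ab_raw[-length(ab_raw)]
  betas <- pmin(pmax(betas, beta_min), beta_max)
  alphas <- 1 - betas
  structure(list(T = as.integer(T), betas = betas, alphas = alphas,
                 alpha_bars = cumprod(alphas),
                 ddim_steps = as.integer(ddim_steps)),
            class = "diffusion_schedule")
}

# cumulative signal level at step t (t = 0 -> 1)
alpha_bar <- function(sched, t) {
  stopifnot(t >= 0L, t <= sched$T)
  if (t == 0L) 1 else sched$alpha_bars[t]
}

#' Loss weights of the composite diffusion objective
#'
#' @param lambda_bond Weight of the bond-consistency loss (default 0.1).
#' @param lambda_valence Weight of the valence-constraint loss (default 0.5).
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_bond = 0.1, lambda_valence = 0.5) {
  stopifnot(lambda_bond >= 0, lambda_valence >= 0)
  structure(list(lambda_bond = lambda_bond, lambda_valence = lambda_valence),
            class = "loss_weights")
}

#' Forward diffusion (corruption) step
#'
#' Coordinates receive the closed-form Gaussian corruption
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#' Categorical atom state, when supplied, is corrupted by uniform resampling
#' with probability \eqn{1 - \bar\alpha_t} (the simplest discrete process
#' consistent with gradual structural corruption; the Gaussian form is only
#' specified for coordinates).
#'
#' @param x0 n x 3 matrix of clean coordinates.
#' @param t Integer timestep in `0..T`.
#' @param eps Standard-normal draw with the shape of `x0`.
#' @param sched A [cosine_beta_schedule()].
#' @param atom_types Optional character vector of atom types to corrupt.
#' @param alphabet Atom alphabet for resampling.
#' @return List with `coords` (x_t) and `atom_types` (possibly corrupted).
#' @export
forward_diffuse <- function(x0, t, eps, sched, atom_types = NULL,
                            alphabet = MOL_ELEMENTS) {
  x0 <- as.matrix(x0)
  if (t < 0L || t > sched$T) stop("t out of range [0, ", sched$T, "]")
  stopifnot(all(dim(eps) == dim(x0)))
  ab <- alpha_bar(sched, t)
  xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
  at <- atom_types
  if (!is.null(atom_types)) {
    flip <- runif(length(atom_types)) < (1 - ab)
    if (any(flip)) {
      at[flip] <- sample(alphabet, sum(flip), replace = TRUE)
    }
  }
  list(coords = xt, atom_types = at)
}

#' Bond-consistency loss
#'
#' Sum over unordered atom pairs of the binary cross-entropy between the
#' predicted bond probability and the indicator that the interatomic distance
#' is below the bond threshold.  Probabilities are clamped to
#' \[1e-7, 1 - 1e-7\].
#'
#' @param bond_probs n x n matrix in \[0,1\] with zero diagonal.
#' @param coords n x 3 coordinate matrix.
#' @param tau Bond distance threshold in Angstrom (default 1.8).
#' @return Non-negative scalar.
#' @export
bond_loss <- function(bond_probs, coords, tau = 1.8) {
  stopifnot(tau > 0)
  bond_probs <- as.matrix(bond_probs)
  if (any(bond_probs < 0) || any(bond_probs > 1)) {
    stop("bond probabilities must lie in [0, 1]")
  }
  D <- as.matrix(stats::dist(coords))
  y <- (D < tau) * 1
  p <- pmin(pmax(bond_probs, 1e-7), 1 - 1e-7)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(bce[upper.tri(bce)])
}

#' Valence-constraint loss
#'
#' Squared hinge on the excess of each atom's predicted bond-probability
#' row sum over its maximum valence:
#' \eqn{\sum_i \max(0, \sum_j \hat b_{ij} - v_{max}(a_i))^2}.
#'
#' @param bond_probs n x n matrix in \[0,1\], zero diagonal.
#' @param atom_types Character vector of atom types.
#' @param table A [valence_table()].
#' @return Non-negative scalar.
#' @export
valence_loss <- function(bond_probs, atom_types, table = valence_table()) {
  bond_probs <- as.matrix(bond_probs)
  unknown <- setdiff(atom_types, names(table$vmax))
  if (length(unknown)) stop("unknown atom type '", unknown[1L], "'")
  vmax <- as.numeric(table$vmax[atom_types])
  excess <- pmax(0, rowSums(bond_probs) - vmax)
  sum(excess^2)
}

#' Composite diffusion training loss
#'
#' \eqn{L = L_{denoise} + \lambda_{bond} L_{bond} + \lambda_{valence}
#' L_{valence}} with default weights 0.1 and 0.5.
#'
#' @param l_denoise,l_bond,l_valence Non-negative loss components.
#' @param w A [loss_weights()].
#' @return Scalar.
#' @export
composite_loss <- function(l_denoise, l_bond, l_valence, w = loss_weights()) {
  stopifnot(l_denoise >= 0, l_bond >= 0, l_valence >= 0)
  l_denoise + w$lambda_bond * l_bond + w$lambda_valence * l_valence
}

# DDIM sub-schedule: uniformly strided kept timesteps from T down to 0
ddim_timesteps <- function(sched, steps) {
  if (steps > sched$T) stop("steps must not exceed T")
  unique(round(seq(sched$T, 0, length.out = steps + 1L)))
}

#' Deterministic DDIM sampling
#'
#' Starting from standard-normal coordinates and a uniform categorical atom
#' state, iterates the deterministic update
#' \eqn{x_{t-1} = \sqrt{\bar\alpha_{t-1}}\hat x_0 +
#' \sqrt{1-\bar\alpha_{t-1}}\,\hat\epsilon} over a uniformly strided
#' sub-schedule, where \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}
#' \hat\epsilon)/\sqrt{\bar\alpha_t}} (the \eqn{\eta = 0} variant; the
#' cumulative \eqn{\bar\alpha} is used throughout).  The final step decodes
#' atom types by argmax of the atom logits and bonds by thresholding the
#' predicted bond probabilities at 0.5.
#'
#' @param params Denoiser parameters from [init_denoiser()].
#' @param n_atoms Number of atoms to generate.
#' @param sched A [cosine_beta_schedule()].
#' @param steps Number of DDIM steps (default `sched$ddim_steps`).
#' @param cond Optional conditioning context from [encode_properties()].
#' @param noise Optional n x 3 initial noise (drawn if NULL).
#' @param atom_init Optional initial atom-type guess (uniform if NULL).
#' @param policy_sigma If positive, inject Gaussian exploration noise of this
#'   standard deviation around the predicted noise at each kept step and
#'   record per-step log-probabilities (the RL rollout mode).
#' @param record Keep per-step transitions (states, actions, log-probs).
#' @return A [molecule_graph()] with `bond_probs` attached; in `record` mode
#'   the transitions are attached as attribute `"transitions"`.
#' @export
ddim_sample <- function(params, n_atoms, sched, steps = sched$ddim_steps,
                        cond = NULL, noise = NULL, atom_init = NULL,
                        policy_sigma = 0, record = FALSE) {
  ts <- ddim_timesteps(sched, steps)
  x <- if (is.null(noise)) {
    matrix(rnorm(n_atoms * 3L), n_atoms, 3L)
  } else as.matrix(noise)
  stopifnot(nrow(x) == n_atoms, ncol(x) == 3L)
  atoms <- if (is.null(atom_init)) {
    sample(params$config$alphabet, n_atoms, replace = TRUE)
  } else atom_init
  transitions <- list()
  out <- NULL
  for (k in seq_len(length(ts) - 1L)) {
    t_cur <- ts[k]; t_prev <- ts[k + 1L]
    out <- denoiser_forward(params, x, atoms, t_cur, sched, cond = cond)
    eps_hat <- out$eps_coords
    action <- eps_hat
    if (policy_sigma > 0) {
      z <- matrix(rnorm(n_atoms * 3L), n_atoms, 3L)
      action <- eps_hat + policy_sigma * z
    }
    if (record) {
      lp <- gaussian_logp(action, eps_hat, max(policy_sigma, 1))
      transitions[[k]] <- list(x = x, atoms = atoms, t = t_cur,
                               action = action, eps_hat = eps_hat, logp = lp)
    }
    ab_t <- alpha_bar(sched, t_cur)
    ab_p <- alpha_bar(sched, t_prev)
    x0_hat <- (x - sqrt(1 - ab_t) * action) / sqrt(ab_t)
    x <- sqrt(ab_p) * x0_hat + sqrt(1 - ab_p) * action
    atoms <- params$config$alphabet[apply(out$atom_logits, 1L, which.max)]
  }
  bp <- out$bond_probs
  diag(bp) <- 0
  D <- as.matrix(stats::dist(x))
  idx <- which(upper.tri(bp) & bp >= 0.5, arr.ind = TRUE)
  bonds <- if (nrow(idx)) {
    data.frame(i = idx[, 1L], j = idx[, 2L], order = 1)
  } else NULL
  mol <- molecule_graph(atoms, x, bonds, bond_probs = bp)
  if (record) attr(mol, "transitions") <- transitions
  mol
}

# log-density of an isotropic Gaussian policy over the denoising direction
gaussian_logp <- function(action, mean, sigma = 1) {
  d <- length(action)
  -0.5 * sum((action - mean)^2) / sigma^2 -
    0.5 * d * log(2 * pi * sigma^2)
}
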