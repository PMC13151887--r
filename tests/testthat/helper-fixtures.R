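# Shared desk-scale objects, built once per test run.

# a small deterministic fixture corpus
fix_corpus <- function(n = 12L, seed = 42L) gen_toy_molecules(n, seed)

# a tiny denoiser for forward-pass properties
tiny_denoiser <- function(seed = 1L) {
  cfg <- denoiser_config(layers = 3L, hidden = 16L, cond_layers = c(2L, 3L),
                         cond_dim = 16L, t_dim = 8L)
  init_denoiser(cfg, seed = seed)
}

# a zero-noise denoiser: the coordinate head is disabled so eps_hat == 0,
# giving a closed-form DDIM trajectory
zero_coord_denoiser <- function(seed = 1L) {
  den <- tiny_denoiser(seed)
  den$coord$Wq <- 0 * den$coord$Wq
  den
}

# desk-scale training configuration (small network, short schedule)
smoke_config <- function() {
  cfg <- default_config()
  cfg$diffusion$T <- 60L
  cfg$diffusion$ddim_steps <- 6L
  cfg$model$layers <- 2L
  cfg$model$hidden <- 16L
  cfg$model$t_dim <- 8L
  cfg$conditioning$layers <- c(1L, 2L)
  cfg$conditioning$model_dim <- 32L
  cfg$conditioning$transformer_layers <- 1L
  cfg$conditioning$heads <- 4L
  cfg$conditioning$encode_dim <- 16L
  cfg$train$batch_size <- 10L
  cfg$train$rollout_atoms <- c(5L, 7L)
  cfg
}

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent exhaustive-pairwise non-dominated sorting oracle (plain loops)
brute_force_ranks <- function(P) {
  n <- nrow(P)
  ranks <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    front <- c()
    for (i in remaining) {
      dominated <- FALSE
      for (j in remaining) {
        if (i == j) next
        if (all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) front <- c(front, i)
    }
    ranks[front] <- r
    remaining <- setdiff(remaining, front)
  }
  ranks
}
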