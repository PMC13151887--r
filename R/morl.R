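#' RL hyperparameter configuration
#'
#' Defaults follow the reference hyperparameter table: PPO clip 0.2, value
#' coefficient 0.5, entropy coefficient 0.01, K = 4 PPO epochs, minibatch 64,
#' GAE lambda 0.95, discount 0.99, learning rates 1e-4 (RL) and 5e-4
#' (diffusion), gradient-norm clip 0.5, replay capacity 10000 with priority
#' exponent 0.6, diversity bonus alpha 0.1, batch mix 70/20/10 (new / buffer /
#' training data) and importance weights clipped to \[0.5, 2\].
#'
#' @param ... Named overrides of any default.
#' @return Object of class `rl_config`.
#' @export
rl_config <- function(...) {
  cfg <- list(clip = 0.2, value_coef = 0.5, entropy_coef = 0.01,
              ppo_epochs = 4L, minibatch = 64L, gae_lambda = 0.95,
              gamma = 0.99, lr_rl = 1e-4, lr_diffusion = 5e-4,
              grad_clip = 0.5, buffer_capacity = 10000L,
              priority_exponent = 0.6, diversity_alpha = 0.1,
              batch_mix = c(new = 0.70, buffer = 0.20, train = 0.10),
              is_clip_range = c(0.5, 2.0))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown rl_config field: ", bad[1L])
  cfg[names(ov)] <- ov
  stopifnot(abs(sum(cfg$batch_mix) - 1) < 1e-9)
  structure(cfg, class = "rl_config")
}

# indices of points (rows, maximization) not dominated by any other row;
# chunked vectorized pairwise dominance
non_dominated_idx <- function(P) {
  N <- nrow(P)
  m <- ncol(P)
  if (N == 1L) return(1L)
  dom <- logical(N)
  chunk <- max(1L, min(N, floor(2e6 / N)))
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    ge <- matrix(TRUE, N, length(idx))
    gt <- matrix(FALSE, N, length(idx))
    for (k in seq_len(m)) {
      ge <- ge & outer(P[, k], P[idx, k], ">=")
      gt <- gt | outer(P[, k], P[idx, k], ">")
    }
    dom[idx] <- colSums(ge & gt) > 0L
  }
  which(!dom)
}

#' Fast non-dominated sorting (NSGA-II ranks)
#'
#' Partitions a set of objective vectors (maximization orientation) into
#' successive Pareto fronts: rank 1 is the non-dominated set, and stripping
#' the rank-k fronts leaves the rank-(k+1) front non-dominated.  Equal points
#' share a front.
#'
#' @param points Numeric matrix (rows = solutions, columns = objectives) or a
#'   list of equal-length vectors.
#' @param max_fronts Stop after this many fronts; remaining points get `NA`
#'   rank (used by [pareto_efficiency()], which only needs the first front).
#' @return Integer vector of Pareto ranks (1 = non-dominated).
#' @export
non_dominated_sort <- function(points, max_fronts = Inf) {
  P <- if (is.list(points)) do.call(rbind, points) else as.matrix(points)
  if (nrow(P) == 0L) stop("empty point set")
  ranks <- rep(NA_integer_, nrow(P))
  remaining <- seq_len(nrow(P))
  r <- 0L
  while (length(remaining) && r < max_fronts) {
    r <- r + 1L
    nd <- non_dominated_idx(P[remaining, , drop = FALSE])
    ranks[remaining[nd]] <- r
    remaining <- remaining[-nd]
  }
  ranks
}

#' Crowding distance within a Pareto front
#'
#' Per point, the sum over objectives of the normalized gap between its
#' sorted neighbours.  Boundary points (extreme in any objective) receive
#' twice the maximum finite interior distance so that the normalized
#' diversity bonus stays bounded (classic NSGA-II assigns them infinity);
#' fronts of size one or two get uniform distance 1.
#'
#' @param front Numeric matrix of rank-equal objective vectors.
#' @return Numeric vector of crowding distances (order matches input rows).
#' @export
crowding_distance <- function(front) {
  F <- as.matrix(front)
  n <- nrow(F)
  if (n <= 2L) return(rep(1, n))
  cd <- numeric(n)
  boundary <- logical(n)
  for (k in seq_len(ncol(F))) {
    ord <- order(F[, k])
    rng <- F[ord[n], k] - F[ord[1L], k]
    boundary[ord[c(1L, n)]] <- TRUE
    if (rng <= 0) next
    inner <- ord[2:(n - 1L)]
    cd[inner] <- cd[inner] + (F[ord[3:n], k] - F[ord[1:(n - 2L)], k]) / rng
  }
  mx <- if (any(!boundary)) max(cd[!boundary]) else 0
  cd[boundary] <- 2 * mx
  cd
}

#' Pareto-based reward assignment for a batch
#'
#' Phase 1 rewards the single active objective (QED) directly.  Phases 2 and
#' 3 use the rank-based reward \eqn{R_{rank} = 1 - (r - 1)/(N - 1)} from
#' NSGA-II non-dominated sorting; phase 3 adds the normalized
#' crowding-distance diversity bonus \eqn{\alpha\, CD / \max(CD)} with
#' \eqn{\alpha = 0.1}.  A singleton batch gets reward 1, and invalid
#' molecules get reward 0 in every phase.
#'
#' @param objectives N x 3 matrix of `(qed, -sa, novelty)` vectors.
#' @param cfg An [rl_config()].
#' @param phase A [curriculum_phase()].
#' @param valid Optional logical vector; `FALSE` entries are forced to
#'   reward 0.
#' @return Object of class `pareto_result`: list with `rank`, `cd`,
#'   `reward`.
#' @export
assign_rewards <- function(objectives, cfg = rl_config(),
                           phase = curriculum_phase(60L), valid = NULL) {
  P <- as.matrix(objectives)
  N <- nrow(P)
  stopifnot(N >= 1L)
  ranks <- non_dominated_sort(P)
  cd <- numeric(N)
  for (r in unique(ranks)) {
    idx <- which(ranks == r)
    cd[idx] <- crowding_distance(P[idx, , drop = FALSE])
  }
  if (phase$id == 1L) {
    reward <- pmin(1, pmax(0, P[, 1L]))
  } else if (N == 1L) {
    reward <- 1
  } else {
    reward <- 1 - (ranks - 1) / (N - 1)
    if (phase$diversity_bonus) {
      mx <- max(cd)
      if (mx > 0) reward <- reward + cfg$diversity_alpha * cd / mx
    }
  }
  if (!is.null(valid)) reward[!valid] <- 0
  structure(list(rank = ranks, cd = cd, reward = reward),
            class = "pareto_result")
}

#' Generalized advantage estimation
#'
#' Backward recursion \eqn{A_t = \delta_t + \gamma\lambda A_{t+1}} with
#' \eqn{\delta_t = r_t + \gamma V(s_{t+1}) - V(s_t)} and terminal value 0.
#'
#' @param rewards Numeric reward sequence.
#' @param values Value estimates aligned with `rewards`.
#' @param gamma Discount (default 0.99).
#' @param lambda GAE mixing (default 0.95).
#' @return Numeric advantage sequence.
#' @export
gae_advantages <- function(rewards, values, gamma = 0.99, lambda = 0.95) {
  if (length(rewards) != length(values)) stop("length mismatch")
  n <- length(rewards)
  next_v <- c(values[-1L], 0)
  deltas <- rewards + gamma * next_v - values
  adv <- numeric(n)
  acc <- 0
  for (t in seq(n, 1L)) {
    acc <- deltas[t] + gamma * lambda * acc
    adv[t] <- acc
  }
  adv
}

#' PPO loss with clipped surrogate and buffer-aware value update
#'
#' The clipped surrogate \eqn{\min(r_t A_t, clip(r_t, 1-\epsilon,
#' 1+\epsilon) A_t)} is averaged over *fresh* samples only; replay-buffer
#' samples contribute solely to the value loss, weighted by importance
#' weights \eqn{\pi_\theta/\pi_{\theta_{old}}} clipped to the configured
#' range.  The total is `policy + value_coef * value - entropy_coef *
#' entropy`.
#'
#' @param logp_new,logp_old Log-probabilities under the current and behaviour
#'   policies.
#' @param advantages Advantage estimates.
#' @param values,returns Value predictions and empirical returns.
#' @param entropy Mean policy entropy (a constant for the fixed-variance
#'   Gaussian policy).
#' @param cfg An [rl_config()].
#' @param is_buffer Logical vector flagging replay-buffer samples (excluded
#'   from the policy gradient).
#' @return List with `total`, `policy`, `value`, `entropy`, and the
#'   per-sample clipped `surrogate` values.
#' @export
ppo_loss <- function(logp_new, logp_old, advantages, values, returns,
                     entropy = 0, cfg = rl_config(), is_buffer = NULL) {
  n <- length(logp_new)
  stopifnot(length(logp_old) == n, length(advantages) == n,
            length(values) == n, length(returns) == n)
  if (is.null(is_buffer)) is_buffer <- rep(FALSE, n)
  ratio <- exp(logp_new - logp_old)
  surr <- pmin(ratio * advantages,
               pmin(pmax(ratio, 1 - cfg$clip), 1 + cfg$clip) * advantages)
  fresh <- !is_buffer
  policy <- if (any(fresh)) -mean(surr[fresh]) else 0
  w <- rep(1, n)
  w[is_buffer] <- pmin(pmax(ratio[is_buffer], cfg$is_clip_range[1L]),
                       cfg$is_clip_range[2L])
  value <- mean(w * (values - returns)^2)
  total <- policy + cfg$value_coef * value - cfg$entropy_coef * entropy
  list(total = total, policy = policy, value = value, entropy = entropy,
       surrogate = surr)
}

# ---- prioritized replay buffer --------------------------------------------

#' Create a prioritized replay buffer
#'
#' @param capacity Maximum number of entries (default 10000).
#' @return Object of class `replay_buffer` (an environment).
#' @export
new_replay_buffer <- function(capacity = 10000L) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$entries <- list()
  b$priorities <- numeric()
  b$inserted <- integer()   # insertion counter per entry (stable tie-break)
  b$counter <- 0L
  class(b) <- "replay_buffer"
  b
}

#' @export
length.replay_buffer <- function(x) length(x$entries)

#' Insert batch results into the replay buffer
#'
#' Each entry's priority is `(1 / rank) * novelty`; when the buffer exceeds
#' capacity, lowest-priority entries are evicted (ties broken by insertion
#' order, oldest first).
#'
#' @param buffer A [new_replay_buffer()].
#' @param entries List of entries; each must carry `rank` and `novelty`
#'   fields (anything else — molecule, objectives, stored log-probabilities,
#'   epoch — rides along).
#' @return The buffer, invisibly (modified in place).
#' @export
buffer_update <- function(buffer, entries) {
  for (e in entries) {
    stopifnot(!is.null(e$rank), !is.null(e$novelty))
    pr <- max((1 / e$rank) * e$novelty, 1e-8)
    buffer$counter <- buffer$counter + 1L
    buffer$entries[[length(buffer$entries) + 1L]] <- e
    buffer$priorities <- c(buffer$priorities, pr)
    buffer$inserted <- c(buffer$inserted, buffer$counter)
  }
  if (length(buffer$entries) > buffer$capacity) {
    keep_n <- buffer$capacity
    ord <- order(-buffer$priorities, -buffer$inserted)  # best first, newer
    keep <- sort(ord[seq_len(keep_n)])
    buffer$entries <- buffer$entries[keep]
    buffer$priorities <- buffer$priorities[keep]
    buffer$inserted <- buffer$inserted[keep]
  }
  invisible(buffer)
}

#' Prioritized sampling without replacement
#'
#' Sampling probability proportional to `priority^alpha` with the configured
#' priority exponent (default 0.6).
#'
#' @param buffer A [new_replay_buffer()].
#' @param k Number of entries to draw.
#' @param alpha Priority exponent.
#' @param seed Optional integer seed for a reproducible draw.
#' @return List of sampled entries (attribute `"index"` carries positions).
#' @export
buffer_sample <- function(buffer, k, alpha = 0.6, seed = NULL) {
  n <- length(buffer$entries)
  if (n == 0L) stop("cannot sample from an empty buffer")
  if (k > n) {
    warning("requested ", k, " samples from buffer of size ", n,
            "; returning all")
    k <- n
  }
  draw <- function() {
    p <- buffer$priorities^alpha
    sample.int(n, k, prob = p / sum(p))
  }
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(buffer$entries[idx], index = idx)
}

#' Compose a mixed training batch
#'
#' Target composition is 70 percent newly generated molecules, 20 percent
#' replay-buffer molecules and 10 percent training data.  The new and buffer
#' shares are rounded to the nearest integer and the training share absorbs
#' the residual (batch 128 -> 90/26/12); shortfalls in the buffer or
#' training pools are backfilled with new samples and noted in the returned
#' counts.
#'
#' @param policy_samples List of freshly generated items.
#' @param buffer A [new_replay_buffer()] (or NULL).
#' @param train_corpus List of training items.
#' @param batch_size Total batch size.
#' @param cfg An [rl_config()].
#' @param seed Optional integer seed for reproducible pool draws.
#' @return List with `new`, `buffer`, `train` (item lists), `counts`
#'   (achieved composition) and `target` (nominal composition).
#' @export
compose_batch <- function(policy_samples, buffer, train_corpus, batch_size,
                          cfg = rl_config(), seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, compose_batch(policy_samples, buffer,
                                         train_corpus, batch_size, cfg)))
  }
  stopifnot(batch_size >= 1L)
  mix <- cfg$batch_mix
  n_new <- round(mix[["new"]] * batch_size)
  n_buf <- round(mix[["buffer"]] * batch_size)
  n_train <- batch_size - n_new - n_buf
  target <- c(new = n_new, buffer = n_buf, train = n_train)
  avail_buf <- if (is.null(buffer)) 0L else length(buffer)
  take_buf <- min(n_buf, avail_buf)
  take_train <- min(n_train, length(train_corpus))
  take_new <- min(batch_size - take_buf - take_train, length(policy_samples))
  buf_items <- if (take_buf > 0L) buffer_sample(buffer, take_buf,
                                                cfg$priority_exponent)
               else list()
  train_items <- if (take_train > 0L) {
    train_corpus[sample.int(length(train_corpus), take_train)]
  } else list()
  new_items <- policy_samples[seq_len(take_new)]
  list(new = new_items, buffer = buf_items, train = train_items,
       counts = c(new = take_new, buffer = take_buf, train = take_train),
       target = target)
}

#' Curriculum phase for an epoch
#'
#' Phase 1 (epochs 1-20) optimizes QED only; phase 2 (epochs 21-50) adds SA
#' and novelty with Pareto ranking; phase 3 (epochs 51+) adds the
#' crowding-distance diversity bonus.  The learning-rate multiplier halves at
#' each transition (`0.5^(phase - 1)`).
#'
#' @param epoch Training epoch (>= 1).
#' @return Object of class `curriculum_phase` with fields `id`,
#'   `epoch_range`, `objectives`, `pareto_ranking`, `diversity_bonus`,
#'   `lr_multiplier`.
#' @export
curriculum_phase <- function(epoch) {
  if (epoch < 1L) stop("epoch must be >= 1")
  if (epoch <= 20L) {
    id <- 1L; rng <- c(1L, 20L); obj <- "qed"
  } else if (epoch <= 50L) {
    id <- 2L; rng <- c(21L, 50L); obj <- c("qed", "sa", "novelty")
  } else {
    id <- 3L; rng <- c(51L, NA_integer_); obj <- c("qed", "sa", "novelty")
  }
  structure(list(id = id, epoch_range = rng, objectives = obj,
                 pareto_ranking = id >= 2L, diversity_bonus = id == 3L,
                 lr_multiplier = 0.5^(id - 1L)),
            class = "curriculum_phase")
}
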