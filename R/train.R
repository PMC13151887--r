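#' @name training
#' @title Joint training: diffusion denoising + PPO with Pareto rewards
#'
#' @description
#' The trainer holds the denoiser, the property conditioner and a small
#' critic, a prioritized replay buffer and the training corpus.  Each epoch:
#' compose a 70/20/10 batch, roll out new molecules by DDIM with a Gaussian
#' exploration policy over the predicted noise (fixed sigma = 1, which makes
#' the PPO probability ratio well defined for the otherwise deterministic
#' sampler), evaluate objectives, assign Pareto-based rewards per curriculum
#' phase, run GAE and K PPO epochs, update the replay buffer, and take
#' diffusion denoising steps on the training-data share of the batch.
#' Learning rates halve at curriculum phase transitions.  One integer seed
#' controls initialization, noise draws and data order.
NULL

critic_features <- function(coords, atoms, t, T, alphabet) {
  A <- matrix(0, length(atoms), length(alphabet))
  A[cbind(seq_along(atoms), match(atoms, alphabet))] <- 1
  matrix(c(colMeans(A), t / T, sqrt(mean(coords^2)), nrow(coords) / 10), 1)
}

init_critic <- function(d_in, seed = 1L, hidden = 32L) {
  with_seed(seed, {
    list(W1 = rmat(d_in, hidden), b1 = matrix(0, 1, hidden),
         W2 = rmat(hidden, 1L), b2 = matrix(0, 1, 1))
  })
}

critic_forward_ad <- function(P, feats, tape) {
  h <- ad_silu(ad_add(ad_matmul(ad_const(tape, feats), P$W1), P$b1))
  ad_add(ad_matmul(h, P$W2), P$b2)
}

critic_value <- function(params, feats) {
  h <- feats %*% params$W1
  h <- sweep(h, 2L, as.numeric(params$b1), "+")
  s <- 1 / (1 + exp(-h))
  as.numeric((h * s) %*% params$W2 + params$b2)
}

# corpus-derived z-scoring statistics for the continuous conditioners
estimate_norm_stats <- function(records) {
  m <- sapply(c("qed", "sa", "logp", "mw"), function(p) {
    vals <- vapply(records, function(r) r[[p]], numeric(1))
    c(mean(vals), max(stats::sd(vals), 1e-3))
  })
  list(mean = m[1L, ], sd = m[2L, ])
}

#' Initialize a training state
#'
#' @param corpus List of [molecule_graph()] training molecules.
#' @param config Full run configuration (see [default_config()]); the
#'   `model`, `diffusion`, `conditioning`, `rl` and `train` sections are
#'   used.
#' @param seed Master integer seed.
#' @return Environment of class `train_state`.
#' @export
init_train_state <- function(corpus, config = default_config(), seed = 42L) {
  stopifnot(length(corpus) >= 1L)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$cfg <- do.call(rl_config, config$rl[setdiff(names(config$rl), NULL)])
  st$seed <- as.integer(seed)
  st$sched <- cosine_beta_schedule(config$diffusion$T,
                                   config$diffusion$ddim_steps)
  st$weights <- loss_weights(config$diffusion$lambda_bond,
                             config$diffusion$lambda_valence)
  st$den_cfg <- denoiser_config(
    layers = config$model$layers, hidden = config$model$hidden,
    cond_layers = config$conditioning$layers,
    cond_dim = config$conditioning$model_dim,
    t_dim = config$model$t_dim, dist_scale = config$model$dist_scale)
  st$den <- init_denoiser(st$den_cfg, seed = derive_seed(seed, 1L))
  st$corpus <- corpus
  st$records <- lapply(corpus, score_properties)
  st$cond <- init_conditioner(
    conditioning_config(
      encode_dim = config$conditioning$encode_dim,
      model_dim = config$conditioning$model_dim,
      transformer_layers = config$conditioning$transformer_layers,
      heads = config$conditioning$heads,
      tolerance = config$conditioning$tolerance),
    seed = derive_seed(seed, 2L),
    norm_stats = estimate_norm_stats(st$records))
  st$critic <- init_critic(length(st$den_cfg$alphabet) + 3L,
                           seed = derive_seed(seed, 3L))
  st$opt_den <- adam_init(st$den[setdiff(names(st$den), "config")])
  st$opt_cond <- adam_init(st$cond[c("tf")])
  st$opt_critic <- adam_init(st$critic)
  st$buffer <- new_replay_buffer(st$cfg$buffer_capacity)
  st$fp_index <- fingerprint_index(corpus)
  st$corpus_smiles <- vapply(corpus, graph_to_smiles, character(1))
  st$logs <- list()
  class(st) <- "train_state"
  st
}

# one denoising-objective step over a micro-batch of clean molecules;
# returns the mean composite loss and applies gradient-accumulated Adam
# updates to the denoiser (and conditioner, through which gradients flow)
diffusion_step <- function(st, mols, lr, update = TRUE) {
  tape <- ad_tape()
  wd <- ad_wrap_params(tape, st$den[setdiff(names(st$den), "config")])
  wc <- ad_wrap_params(tape, st$cond[c("tf")])
  total <- NULL
  for (mol in mols) {
    t <- sample.int(st$sched$T, 1L)
    eps <- matrix(rnorm(mol$n * 3L), mol$n, 3L)
    xt <- sqrt(alpha_bar(st$sched, t)) * mol$coords +
      sqrt(1 - alpha_bar(st$sched, t)) * eps
    rec <- suppressWarnings(score_properties(mol))
    tok <- conditioning_tokens(st$cond, list(qed = rec$qed, mw = rec$mw))
    ctx <- conditioner_encode_ad(wc$nodes, st$cond$config,
                                 ad_const(tape, unclass(tok)), tape)
    out <- denoiser_forward_ad(wd$nodes, st$den_cfg, xt, mol$atom_types, t,
                               st$sched, cond_c = ctx, tape = tape)
    l_den <- ad_mean(ad_square(ad_sub(ad_const(tape, eps), out$eps_coords)))
    # bond/valence targets come from the clean geometry
    D <- as.matrix(stats::dist(mol$coords))
    y <- (D < valence_table()$bond_threshold) * 1
    diag(y) <- 0
    p <- ad_clip(out$bond_probs, 1e-7, 1 - 1e-7)
    bce <- ad_scale(ad_add(ad_emul(ad_const(tape, y), ad_log(p)),
                           ad_emul(ad_const(tape, 1 - y),
                                   ad_log(ad_sub(ad_const(tape, matrix(1, mol$n, mol$n)), p)))),
                    -1)
    mask <- upper.tri(matrix(0, mol$n, mol$n)) * 1
    l_bond <- ad_sum(ad_emul(bce, ad_const(tape, mask)))
    vmax <- as.numeric(valence_table()$vmax[mol$atom_types])
    excess <- ad_relu(ad_sub(ad_rowsums(out$bond_probs),
                             ad_const(tape, matrix(vmax, ncol = 1L))))
    l_val <- ad_sum(ad_square(excess))
    l <- ad_add(l_den, ad_add(ad_scale(l_bond, st$weights$lambda_bond),
                              ad_scale(l_val, st$weights$lambda_valence)))
    total <- if (is.null(total)) l else ad_add(total, l)
  }
  loss <- ad_scale(total, 1 / length(mols))
  ad_backward(loss)
  if (update) {
    gd <- ad_grads(wd)
    res <- adam_step(st$den[setdiff(names(st$den), "config")], gd,
                     st$opt_den, lr, clip = st$cfg$grad_clip)
    st$den[names(res$params)] <- res$params
    st$opt_den <- res$state
    gc2 <- ad_grads(wc)
    res2 <- adam_step(st$cond[c("tf")], gc2, st$opt_cond, lr,
                      clip = st$cfg$grad_clip)
    st$cond[names(res2$params)] <- res2$params
    st$opt_cond <- res2$state
  }
  ad_val(loss)
}

#' Run seeded diffusion-only smoke training
#'
#' Takes `steps` gradient steps of the composite denoising loss on random
#' micro-batches of the corpus.  Used for loss-trend diagnostics.
#'
#' @param st A [init_train_state()].
#' @param steps Number of gradient steps.
#' @param batch Micro-batch size.
#' @param seed Integer seed.
#' @return Numeric vector of per-step composite losses.
#' @export
train_diffusion <- function(st, steps, batch = 2L, seed = st$seed) {
  with_seed(derive_seed(seed, 99L), {
    lr <- st$cfg$lr_diffusion
    vapply(seq_len(steps), function(i) {
      mols <- st$corpus[sample.int(length(st$corpus), batch, replace = TRUE)]
      diffusion_step(st, mols, lr)
    }, numeric(1))
  })
}

# evaluate rollout molecules: validity, properties, novelty, objectives
evaluate_rollouts <- function(st, mols) {
  n <- length(mols)
  valid <- logical(n)
  objs <- matrix(0, n, 3L,
                 dimnames = list(NULL, c("qed", "neg_sa", "novelty")))
  novelty <- numeric(n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    chk <- check_validity(mols[[i]])
    valid[i] <- chk$valid
    novelty[i] <- novelty_score(mols[[i]], st$fp_index)
    if (valid[i]) {
      # out-of-vocabulary descriptor clamping is routine during rollouts
      recs[[i]] <- suppressWarnings(score_properties(mols[[i]]))
      objs[i, ] <- objective_vector(recs[[i]], novelty[i])
    } else {
      objs[i, ] <- c(0, -10, novelty[i])
    }
  }
  list(valid = valid, objectives = objs, novelty = novelty, records = recs)
}

# PPO update over recorded transitions; buffer transitions feed only the
# value loss (their importance weight is a clipped constant multiplier, so
# the policy head receives exactly zero gradient from them)
ppo_update <- function(st, transitions, lr) {
  cfg <- st$cfg
  n <- length(transitions)
  if (!n) return(list(policy = 0, value = 0, entropy = 0))
  comps <- c(policy = 0, value = 0, entropy = 0)
  nmb <- 0L
  for (k in seq_len(cfg$ppo_epochs)) {
    ord <- sample.int(n)
    mb_size <- min(cfg$minibatch, n)
    starts <- seq(1L, n, by = mb_size)
    for (s in starts) {
      idx <- ord[s:min(n, s + mb_size - 1L)]
      mb <- transitions[idx]
      fresh <- !vapply(mb, `[[`, logical(1), "is_buffer")
      adv <- vapply(mb, `[[`, numeric(1), "advantage")
      if (sum(fresh) > 1L && stats::sd(adv[fresh]) > 1e-8) {
        adv[fresh] <- (adv[fresh] - mean(adv[fresh])) / stats::sd(adv[fresh])
      }
      tape <- ad_tape()
      wd <- ad_wrap_params(tape, st$den[setdiff(names(st$den), "config")])
      wcr <- ad_wrap_params(tape, st$critic)
      pol_terms <- NULL
      val_terms <- NULL
      ent <- 0
      for (j in seq_along(mb)) {
        tr <- mb[[j]]
        feats <- critic_features(tr$x, tr$atoms, tr$t, st$sched$T,
                                 st$den_cfg$alphabet)
        v <- critic_forward_ad(wcr$nodes, feats, tape)
        wgt <- 1
        if (tr$is_buffer) {
          # numeric ratio for the importance weight (constant multiplier)
          outn <- denoiser_forward(st$den, tr$x, tr$atoms, tr$t, st$sched,
                                   cond = tr$cond)
          lp_now <- gaussian_logp(tr$action, outn$eps_coords, 1)
          wgt <- min(max(exp(lp_now - tr$logp), cfg$is_clip_range[1L]),
                     cfg$is_clip_range[2L])
        } else {
          out <- denoiser_forward_ad(wd$nodes, st$den_cfg, tr$x, tr$atoms,
                                     tr$t, st$sched,
                                     cond_c = if (is.null(tr$cond)) NULL else
                                       ad_const(tape, tr$cond),
                                     tape = tape)
          diff <- ad_sub(ad_const(tape, tr$action), out$eps_coords)
          lp_new <- ad_scale(ad_sum(ad_square(diff)), -0.5)
          lp_old_core <- -0.5 * sum((tr$action - tr$eps_hat)^2)
          ratio <- ad_exp(ad_sub(lp_new, ad_const(tape, lp_old_core)))
          surr <- ad_min2(ad_scale(ratio, adv[j]),
                          ad_scale(ad_clip(ratio, 1 - cfg$clip, 1 + cfg$clip),
                                   adv[j]))
          pol_terms <- if (is.null(pol_terms)) surr else
            ad_add(pol_terms, surr)
          d <- length(tr$action)
          ent <- ent + 0.5 * d * (1 + log(2 * pi))
        }
        vt <- ad_scale(ad_square(ad_sub(v, ad_const(tape, matrix(tr$ret)))),
                       wgt)
        val_terms <- if (is.null(val_terms)) vt else ad_add(val_terms, vt)
      }
      n_fresh <- sum(fresh)
      loss <- ad_scale(val_terms, cfg$value_coef / length(mb))
      if (!is.null(pol_terms) && n_fresh > 0L) {
        loss <- ad_add(loss, ad_scale(pol_terms, -1 / n_fresh))
      }
      if (!is.finite(ad_val(loss))) {
        stop("non-finite PPO loss; epoch aborted (minibatch of ",
             length(mb), " transitions)")
      }
      ad_backward(loss)
      res <- adam_step(st$den[setdiff(names(st$den), "config")],
                       ad_grads(wd), st$opt_den, lr, clip = cfg$grad_clip)
      st$den[names(res$params)] <- res$params
      st$opt_den <- res$state
      resc <- adam_step(st$critic, ad_grads(wcr), st$opt_critic, lr,
                        clip = cfg$grad_clip)
      st$critic <- resc$params
      st$opt_critic <- resc$state
      ent_mean <- if (n_fresh > 0L) ent / n_fresh else 0
      comps <- comps + c(policy = if (is.null(pol_terms)) 0 else
                           -ad_val(pol_terms) / max(1L, n_fresh),
                         value = ad_val(val_terms) / length(mb),
                         entropy = ent_mean)
      nmb <- nmb + 1L
    }
  }
  as.list(comps / max(1L, nmb))
}

#' Run one training epoch
#'
#' Executes the per-iteration loop: batch composition, DDIM policy rollouts,
#' objective evaluation, Pareto reward assignment per curriculum phase, GAE,
#' K PPO epochs, replay-buffer update and diffusion steps on the
#' training-data share.  Appends a structured log entry to the state.
#'
#' @param st A [init_train_state()] (modified in place).
#' @param epoch Epoch number (drives the curriculum phase and learning-rate
#'   halving).
#' @return The epoch log entry (list), invisibly also appended to
#'   `st$logs`.
#' @export
train_epoch <- function(st, epoch) {
  cfg <- st$cfg
  tc <- st$config$train
  phase <- curriculum_phase(epoch)
  lr_rl <- cfg$lr_rl * phase$lr_multiplier
  lr_diff <- cfg$lr_diffusion * phase$lr_multiplier
  log_entry <- NULL
  with_seed(derive_seed(st$seed, 1000L + epoch), {
    for (it in seq_len(tc$iterations)) {
      B <- tc$batch_size
      n_new <- round(cfg$batch_mix[["new"]] * B)
      ctx <- encode_properties(st$cond, NULL)
      rollouts <- lapply(seq_len(n_new), function(i) {
        na <- sample(seq(tc$rollout_atoms[1L], tc$rollout_atoms[2L]), 1L)
        ddim_sample(st$den, na, st$sched, steps = st$sched$ddim_steps,
                    cond = ctx, policy_sigma = 1, record = TRUE)
      })
      ev <- evaluate_rollouts(st, rollouts)
      bm <- compose_batch(rollouts, st$buffer, st$corpus, B, cfg)
      pr <- assign_rewards(ev$objectives, cfg, phase, valid = ev$valid)
      # per-episode GAE on recorded transitions (terminal Pareto reward)
      transitions <- list()
      for (i in seq_along(rollouts)) {
        trs <- attr(rollouts[[i]], "transitions")
        Tn <- length(trs)
        vals <- vapply(trs, function(tr) {
          critic_value(st$critic,
                       critic_features(tr$x, tr$atoms, tr$t, st$sched$T,
                                       st$den_cfg$alphabet))
        }, numeric(1))
        rew <- c(rep(0, Tn - 1L), pr$reward[i])
        adv <- gae_advantages(rew, vals, cfg$gamma, cfg$gae_lambda)
        ret <- adv + vals
        # sub-sample steps for the PPO update to bound the epoch cost
        keep <- unique(round(seq(1L, Tn,
                                 length.out = min(Tn, tc$ppo_sample_steps))))
        for (k in keep) {
          tr <- trs[[k]]
          transitions[[length(transitions) + 1L]] <- list(
            x = tr$x, atoms = tr$atoms, t = tr$t, action = tr$action,
            eps_hat = tr$eps_hat,
            logp = tr$logp, advantage = adv[k], ret = ret[k],
            cond = ctx, is_buffer = FALSE)
        }
      }
      # buffer share: value-only transitions
      for (e in bm$buffer) {
        for (tr in e$transitions) {
          transitions[[length(transitions) + 1L]] <- c(
            tr, list(advantage = 0, ret = e$ret, cond = e$cond,
                     is_buffer = TRUE))
        }
      }
      ppo <- ppo_update(st, transitions, lr_rl)
      # diffusion steps on the training-data share, in accumulation chunks
      dl <- NA_real_
      if (length(bm$train)) {
        chunks <- split(bm$train,
                        ceiling(seq_along(bm$train) / max(1L, tc$grad_accum)))
        dl <- mean(vapply(chunks, function(ch) {
          diffusion_step(st, ch, lr_diff)
        }, numeric(1)))
      }
      # replay buffer update with the fresh molecules
      entries <- lapply(seq_along(rollouts), function(i) {
        trs <- attr(rollouts[[i]], "transitions")
        keep <- trs[unique(round(seq(1L, length(trs), length.out = 2L)))]
        keep <- lapply(keep, function(tr) {
          list(x = tr$x, atoms = tr$atoms, t = tr$t, action = tr$action,
               logp = tr$logp)
        })
        list(mol = rollouts[[i]], objectives = ev$objectives[i, ],
             rank = pr$rank[i], novelty = ev$novelty[i],
             logp = trs[[length(trs)]]$logp, epoch = epoch,
             ret = pr$reward[i], cond = ctx, transitions = keep)
      })
      buffer_update(st$buffer, entries)
      if (!is.finite(ppo$value) || (!is.na(dl) && !is.finite(dl))) {
        stop("non-finite loss at epoch ", epoch, "; diagnostic: ",
             jsonlite::toJSON(list(ppo = ppo, diffusion = dl),
                              auto_unbox = TRUE))
      }
      log_entry <- list(
        epoch = epoch, phase = phase$id, lr_rl = lr_rl,
        lr_diffusion = lr_diff,
        batch_counts = as.list(bm$counts), batch_target = as.list(bm$target),
        reward_mean = mean(pr$reward), reward_max = max(pr$reward),
        reward_min = min(pr$reward), n_valid = sum(ev$valid),
        front_size = sum(pr$rank == 1L), diffusion_loss = dl,
        ppo_policy = ppo$policy, ppo_value = ppo$value,
        entropy = ppo$entropy, buffer_size = length(st$buffer))
      st$logs[[length(st$logs) + 1L]] <- log_entry
    }
  })
  invisible(log_entry)
}
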