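test_that("non-dominated sorting handles degenerate and structured inputs", {
  expect_identical(non_dominated_sort(matrix(c(1, 2, 3), 1)), 1L)
  # distinct points with equal coordinate sums are mutually non-dominating
  withr::local_seed(1)
  P <- matrix(runif(30), 10, 3)
  P <- P / rowSums(P) * 2
  expect_true(all(non_dominated_sort(P) == 1L))
  # equal points share a front
  Q <- rbind(c(1, 1), c(1, 1), c(0.5, 0.5))
  expect_identical(non_dominated_sort(Q), c(1L, 1L, 2L))
  # a strictly dominated chain has one point per front
  chain <- matrix(rep(10:1, 3), 10, 3)
  expect_identical(non_dominated_sort(chain), 1:10)
  expect_error(non_dominated_sort(matrix(numeric(), 0, 3)), "empty")
})

test_that("sorting equals the exhaustive pairwise oracle on random instances", {
  withr::local_seed(99)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    m <- sample(2:4, 1)
    # mix continuous and low-resolution (tie-rich) instances
    P <- if (i %% 3 == 0) {
      matrix(sample(0:4, n * m, replace = TRUE), n, m)
    } else {
      matrix(runif(n * m), n, m)
    }
    expect_identical(non_dominated_sort(P), brute_force_ranks(P))
  }
  # a few larger instances
  for (i in 1:10) {
    P <- matrix(runif(200 * 3), 200, 3)
    expect_identical(non_dominated_sort(P), brute_force_ranks(P))
  }
})

test_that("crowding distance matches hand computation and conventions", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(1, 1))
  front <- rbind(c(0, 1), c(0.5, 0.5), c(1, 0))
  cd <- crowding_distance(front)
  expect_equal(cd[2], 2)            # middle point: normalized gaps 1 + 1
  expect_equal(cd[c(1, 3)], c(4, 4))  # boundaries: twice max interior
  # order equivariance
  p <- c(3, 1, 2)
  expect_equal(crowding_distance(front[p, ]), cd[p])
})

test_that("reward assignment follows the rank formula and phase rules", {
  cfg <- rl_config()
  ph2 <- curriculum_phase(30L)
  ph3 <- curriculum_phase(60L)
  chain <- matrix(rep(5:1, 3), 5, 3)   # ranks 1..5
  r2 <- assign_rewards(chain, cfg, ph2)
  expect_equal(r2$reward, 1 - (1:5 - 1) / 4)   # endpoints 1 and 0
  expect_equal(r2$reward[3], 0.5)              # N = 5, r = 3
  # phase 3 adds the normalized crowding bonus; max-CD molecule gets +0.1
  withr::local_seed(8)
  P <- matrix(runif(30), 10, 3)
  r3 <- assign_rewards(P, cfg, ph3)
  i_max <- which.max(r3$cd)
  rank_part <- 1 - (r3$rank - 1) / 9
  expect_equal(r3$reward[i_max], rank_part[i_max] + 0.1, tolerance = 1e-12)
  expect_true(all(r3$reward >= 0 & r3$reward <= 1.1))
  # rank-1 rewards dominate lower fronts' rank rewards
  expect_true(min(rank_part[r3$rank == 1]) >= max(rank_part[r3$rank > 1]))
  # phase 1: QED passthrough; singleton batch; invalid forced to zero
  r1 <- assign_rewards(rbind(c(0.7, -3, 0.9)), cfg, curriculum_phase(5L))
  expect_equal(r1$reward, 0.7)
  rs <- assign_rewards(rbind(c(0.7, -3, 0.9)), cfg, ph2)
  expect_equal(rs$reward, 1)
  ri <- assign_rewards(chain, cfg, ph2, valid = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ri$reward[2], 0)
})

test_that("GAE matches hand recursion and closed-form reductions", {
  expect_equal(gae_advantages(1, 0), 1)
  expect_equal(gae_advantages(c(0, 1), c(0, 0)), c(0.99 * 0.95, 1))
  expect_equal(gae_advantages(rep(0, 5), rep(0, 5)), rep(0, 5))
  withr::local_seed(10)
  r <- rnorm(6); v <- rnorm(6)
  # lambda = 0 reduces to one-step TD residuals
  td <- r + 0.99 * c(v[-1], 0) - v
  expect_equal(gae_advantages(r, v, 0.99, 0), td, tolerance = 1e-12)
  # gamma = lambda = 1 reduces to reward-to-go minus baseline
  expect_equal(gae_advantages(r, v, 1, 1), rev(cumsum(rev(r))) - v,
               tolerance = 1e-12)
  expect_error(gae_advantages(1:3, 1:2), "length mismatch")
})

test_that("PPO clipped surrogate matches hand arithmetic", {
  cfg <- rl_config()
  # ratio 1, A = 1: surrogate 1
  expect_equal(ppo_loss(0, 0, 1, 0, 0, cfg = cfg)$surrogate, 1)
  # ratio 2, A = 1, clip 0.2: min(2, 1.2) = 1.2
  expect_equal(ppo_loss(log(2), 0, 1, 0, 0, cfg = cfg)$surrogate, 1.2)
  # ratio 0.5, A = -1: min(-0.5, -0.8) = -0.8
  expect_equal(ppo_loss(log(0.5), 0, -1, 0, 0, cfg = cfg)$surrogate, -0.8)
  # buffer samples are excluded from the policy term but enter the value term
  out <- ppo_loss(c(0, 0), c(0, 0), c(1, 1), c(0, 0), c(1, 2),
                  cfg = cfg, is_buffer = c(FALSE, TRUE))
  expect_equal(out$policy, -1)
  expect_equal(out$value, mean(c(1, 4)))
})

test_that("replay buffer priorities, capacity and eviction are correct", {
  b <- new_replay_buffer(5L)
  mk <- function(rank, nov, id) list(rank = rank, novelty = nov, id = id)
  buffer_update(b, list(mk(2, 0.8, 1)))
  expect_equal(b$priorities, 0.4)       # (1/2) x 0.8
  buffer_update(b, list(mk(1, 1, 2)))
  expect_equal(max(b$priorities), 1.0)  # maximal priority
  for (k in 3:7) buffer_update(b, list(mk(1, k / 10, k)))
  expect_length(b, 5L)                  # capacity respected
  # the minimum-priority entries were evicted, priority order preserved
  expect_true(min(b$priorities) >= 0.4)
  ids <- vapply(b$entries, `[[`, numeric(1), "id")
  expect_false(1 %in% ids)              # lowest priority (0.4 tie, oldest)
})

test_that("prioritized sampling follows priority^alpha probabilities", {
  b <- new_replay_buffer(10L)
  for (k in 1:4) buffer_update(b, list(list(rank = 1, novelty = 1, id = k)))
  # uniform priorities: empirical first-draw frequencies are uniform
  withr::local_seed(123)
  draws <- replicate(1e4, attr(buffer_sample(b, 1L), "index"))
  tab <- table(factor(draws, levels = 1:4))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  # zero-priority entry is never drawn first against a positive one
  b2 <- new_replay_buffer(10L)
  buffer_update(b2, list(list(rank = 1, novelty = 1, id = 1),
                         list(rank = 1e8, novelty = 1e-8, id = 2)))
  draws2 <- replicate(500, b2$entries[[attr(buffer_sample(b2, 1L), "index")]]$id)
  expect_true(all(draws2 == 1))
  # fixed seed reproduces the sample
  s1 <- attr(buffer_sample(b, 3L, seed = 42L), "index")
  s2 <- attr(buffer_sample(b, 3L, seed = 42L), "index")
  expect_identical(s1, s2)
  expect_warning(buffer_sample(b, 10L), "returning all")
})

test_that("batch composition rounds 70/20/10 and backfills shortfalls", {
  cfg <- rl_config()
  pool <- as.list(1:200)
  b <- new_replay_buffer(100L)
  for (k in 1:50) buffer_update(b, list(list(rank = 1, novelty = 0.5, id = k)))
  bm <- compose_batch(pool, b, as.list(1:50), 128L, cfg, seed = 1L)
  expect_equal(unname(bm$counts), c(90, 26, 12))
  bm10 <- compose_batch(pool, b, as.list(1:50), 10L, cfg, seed = 1L)
  expect_equal(unname(bm10$counts), c(7, 2, 1))
  # empty buffer: the buffer share is backfilled with new samples
  bm_e <- compose_batch(pool, NULL, as.list(1:50), 128L, cfg, seed = 1L)
  expect_equal(unname(bm_e$counts), c(116, 0, 12))
  expect_equal(sum(bm_e$counts), 128)
})

test_that("curriculum phases follow the printed epoch ranges", {
  p1 <- curriculum_phase(10L)
  expect_identical(p1$id, 1L)
  expect_identical(p1$objectives, "qed")
  expect_false(p1$pareto_ranking)
  p2 <- curriculum_phase(21L)
  expect_identical(p2$id, 2L)
  expect_true(p2$pareto_ranking)
  expect_false(p2$diversity_bonus)
  expect_identical(curriculum_phase(50L)$id, 2L)
  p3 <- curriculum_phase(51L)
  expect_identical(p3$id, 3L)
  expect_true(p3$diversity_bonus)
  expect_equal(p3$lr_multiplier, 0.25)
  expect_equal(curriculum_phase(20L)$id, 1L)
  expect_error(curriculum_phase(0L))
})
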