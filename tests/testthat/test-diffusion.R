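test_that("cosine schedule respects the clipped variance range", {
  sc <- cosine_beta_schedule(1000L)
  expect_equal(sc$betas[1], 1e-4)
  expect_equal(sc$betas[1000], 0.02)
  expect_true(all(sc$betas >= 1e-4 & sc$betas <= 0.02))
  expect_true(all(diff(sc$alpha_bars) < 0))
  expect_equal(moldiffrl:::alpha_bar(sc, 0L), 1)
  expect_error(cosine_beta_schedule(1L), "at least 2")
})

test_that("forward diffusion preserves the variance identity", {
  sc <- cosine_beta_schedule(100L)
  x0 <- matrix(rnorm(30), 10, 3)
  # t = 0 is the identity
  out0 <- forward_diffuse(x0, 0L, matrix(rnorm(30), 10, 3), sc)
  expect_identical(out0$coords, x0)
  expect_error(forward_diffuse(x0, 101L, matrix(0, 10, 3), sc), "range")

  # standardized x0: Var(x_t) ~ 1 at any t (alpha_bar + (1 - alpha_bar) = 1)
  withr::local_seed(11)
  x0 <- matrix(rnorm(1e4), ncol = 1)
  x0 <- (x0 - mean(x0)) / sd(x0)
  x0 <- cbind(x0, 0, 0)
  for (t in c(10L, 50L, 95L)) {
    xt <- forward_diffuse(x0, t, matrix(rnorm(3e4), ncol = 3), sc)$coords
    expect_equal(var(xt[, 1]), 1, tolerance = 0.05)
  }
  # near t = T correlation with x0 is about zero
  xt <- forward_diffuse(x0, 100L, matrix(rnorm(3e4), ncol = 3), sc)$coords
  expect_lt(abs(cor(xt[, 1], x0[, 1])), sqrt(moldiffrl:::alpha_bar(sc, 100L)) + 0.05)
})

test_that("bond and valence losses match closed forms", {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  # perfect prediction contributes 0
  bp <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(bond_loss(bp, coords), 0, tolerance = 1e-6)
  # b = 0.5 contributes ln 2
  bp[1, 2] <- bp[2, 1] <- 0.5
  expect_equal(bond_loss(bp, coords), log(2), tolerance = 1e-12)
  # confident wrong prediction at 2.5 A contributes -ln(0.1)
  coords2 <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  bp2 <- matrix(c(0, 0.9, 0.9, 0), 2, 2)
  expect_equal(bond_loss(bp2, coords2), -log(0.1), tolerance = 1e-12)
  expect_error(bond_loss(matrix(c(0, 2, 2, 0), 2, 2), coords), "\\[0, 1\\]")

  # valence hinge squares
  mk <- function(rowsum, n) {
    m <- matrix(rowsum / (n - 1), n, n); diag(m) <- 0; m
  }
  # carbon rows summing to 5 contribute (5 - 4)^2 = 1 each
  expect_equal(valence_loss(mk(5, 7), rep("C", 7)), 7)
  # inactive hinge at row sum 3.5
  expect_equal(valence_loss(mk(3.5, 6), rep("C", 6)), 0)
  # nitrogen row sum 4.5 contributes (4.5 - 3)^2 = 2.25
  expect_equal(valence_loss(mk(4.5, 6), rep("N", 6)), 6 * 2.25)
  expect_error(valence_loss(mk(1, 2), c("C", "Xx")), "unknown atom type")
})

test_that("losses match a scalar loop-based reference on random inputs", {
  withr::local_seed(4)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    bp <- matrix(runif(n * n), n, n)
    bp <- (bp + t(bp)) / 2; diag(bp) <- 0
    coords <- matrix(rnorm(n * 3), n, 3)
    at <- sample(c("C", "N", "O"), n, replace = TRUE)
    # loop-based reference
    ref_b <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      y <- as.numeric(d < 1.8)
      p <- min(max(bp[i, j], 1e-7), 1 - 1e-7)
      ref_b <- ref_b - (y * log(p) + (1 - y) * log(1 - p))
    }
    ref_v <- 0
    vt <- valence_table()
    for (i in 1:n) {
      ref_v <- ref_v + max(0, sum(bp[i, ]) - vt$vmax[[at[i]]])^2
    }
    expect_equal(bond_loss(bp, coords), ref_b, tolerance = 1e-10)
    expect_equal(valence_loss(bp, at), ref_v, tolerance = 1e-10)
  }
})

test_that("composite loss is the stated weighted sum", {
  expect_equal(composite_loss(1, 2, 3), 2.7)
  expect_equal(composite_loss(0, 0, 0), 0)
  eps <- matrix(rnorm(9), 3, 3)
  expect_equal(mean((eps - eps)^2), 0)
})

test_that("denoiser is SE(3)-equivariant and permutation-consistent", {
  den <- tiny_denoiser(seed = 8L)
  sc <- cosine_beta_schedule(60L, 6L)
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    X <- sweep(X, 2, colMeans(X))
    at <- sample(c("C", "N", "O", "F"), n, replace = TRUE)
    o <- denoiser_forward(den, X, at, 7L, sc)
    for (rr in 1:5) {
      R <- random_rotation()
      o2 <- denoiser_forward(den, X %*% t(R), at, 7L, sc)
      expect_lt(max(abs(o2$eps_coords - o$eps_coords %*% t(R))), 1e-5)
      expect_lt(max(abs(o2$atom_logits - o$atom_logits)), 1e-5)
      expect_lt(max(abs(o2$bond_probs - o$bond_probs)), 1e-5)
    }
    # translation invariance (inputs are centred internally)
    o3 <- denoiser_forward(den, X + 3.2, at, 7L, sc)
    expect_lt(max(abs(o3$eps_coords - o$eps_coords)), 1e-8)
    # permutation equivariance
    p <- sample(n)
    o4 <- denoiser_forward(den, X[p, , drop = FALSE], at[p], 7L, sc)
    expect_lt(max(abs(o4$eps_coords - o$eps_coords[p, , drop = FALSE])), 1e-8)
    expect_lt(max(abs(o4$bond_probs - o$bond_probs[p, p])), 1e-8)
  }
})

test_that("DDIM with a zero denoiser follows the closed-form trajectory", {
  den <- zero_coord_denoiser()
  sc <- cosine_beta_schedule(60L, 6L)
  withr::local_seed(3)
  noise <- matrix(rnorm(15), 5, 3)
  mol <- ddim_sample(den, 5L, sc, steps = 6L, noise = noise,
                     atom_init = rep("C", 5), record = TRUE)
  ts <- moldiffrl:::ddim_timesteps(sc, 6L)
  # hand recursion: x_{t-1} = sqrt(ab_prev / ab_t) x_t
  x <- noise
  for (k in seq_len(length(ts) - 1L)) {
    x <- sqrt(moldiffrl:::alpha_bar(sc, ts[k + 1L]) /
                moldiffrl:::alpha_bar(sc, ts[k])) * x
  }
  expect_equal(mol$coords, sweep(x, 2, colMeans(x)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # sub-schedule consistency: full- and sub-schedule agree at shared steps
  m_full <- ddim_sample(den, 5L, sc, steps = 60L, noise = noise,
                        atom_init = rep("C", 5), record = TRUE)
  tr6 <- attr(mol, "transitions")
  tr60 <- attr(m_full, "transitions")
  t60 <- vapply(tr60, `[[`, numeric(1), "t")
  for (tr in tr6) {
    j <- match(tr$t, t60)
    expect_equal(tr$x, tr60[[j]]$x, tolerance = 1e-10)
  }
})

test_that("DDIM sampling is deterministic given the seed", {
  den <- tiny_denoiser()
  sc <- cosine_beta_schedule(60L, 6L)
  m1 <- withr::with_seed(9, ddim_sample(den, 6L, sc))
  m2 <- withr::with_seed(9, ddim_sample(den, 6L, sc))
  expect_identical(m1$coords, m2$coords)
  expect_identical(m1$atom_types, m2$atom_types)
  expect_error(ddim_sample(den, 4L, sc, steps = 100L), "exceed")
})
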