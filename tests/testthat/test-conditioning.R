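test_that("sinusoidal encoding matches its closed form and is smooth", {
  pe <- sinusoidal_encode(0, 8L)
  expect_equal(pe[c(1, 3, 5, 7)], rep(0, 4))  # sine slots
  expect_equal(pe[c(2, 4, 6, 8)], rep(1, 4))  # cosine slots
  expect_equal(sinusoidal_encode(1, 64L)[1], sin(1), tolerance = 1e-12)
  # smoothness: encoding difference vanishes with the perturbation
  d1 <- sqrt(sum((sinusoidal_encode(2, 64L) - sinusoidal_encode(2 + 1e-3, 64L))^2))
  d2 <- sqrt(sum((sinusoidal_encode(2, 64L) - sinusoidal_encode(2 + 1e-6, 64L))^2))
  expect_lt(d2, d1 / 100)
  expect_error(sinusoidal_encode(1, 7L))
})

test_that("discrete embeddings have vocabulary-sized tables and clamp", {
  cond <- init_conditioner(conditioning_config(model_dim = 64L, heads = 4L,
                                               transformer_layers = 2L),
                           seed = 3L)
  expect_identical(nrow(cond$tables$ring_count), 7L)    # 0..6
  expect_identical(nrow(cond$tables$aromatic_rings), 5L)
  expect_identical(nrow(cond$tables$hbd), 6L)
  expect_identical(nrow(cond$tables$hba), 11L)
  v1 <- embed_discrete(cond, "ring_count", 3L)
  expect_identical(v1, embed_discrete(cond, "ring_count", 3L))
  expect_warning(v2 <- embed_discrete(cond, "hba", 12L), "clamped")
  expect_identical(v2, embed_discrete(cond, "hba", 10L))
  expect_error(embed_discrete(cond, "charge", 1L), "unknown discrete property")
})

test_that("property encoding is shape-correct, deterministic and order-insensitive", {
  cond <- init_conditioner(conditioning_config(model_dim = 64L, heads = 4L,
                                               transformer_layers = 2L),
                           seed = 5L)
  c1 <- encode_properties(cond, list(qed = 0.8, mw = 350, ring_count = 2L))
  expect_identical(dim(unclass(c1)), c(3L, 64L))
  expect_identical(attr(c1, "props"), c("qed", "mw", "ring_count"))
  # permuting the input order leaves the output rows identical
  c2 <- encode_properties(cond, list(ring_count = 2L, mw = 350, qed = 0.8))
  expect_identical(unclass(c1), unclass(c2))
  expect_identical(unclass(c1),
                   unclass(encode_properties(cond, list(qed = 0.8, mw = 350,
                                                        ring_count = 2L))))
  # null token path for unconditioned generation
  c0 <- encode_properties(cond, NULL)
  expect_identical(nrow(unclass(c0)), 1L)
  expect_error(encode_properties(cond, list()), "empty target")
})

test_that("cross-attention reduces to known closed forms", {
  withr::local_seed(2)
  d <- 8L
  h <- matrix(rnorm(5 * d), 5, d)
  w <- list(WQ = matrix(rnorm(d * d), d), WK = matrix(rnorm(d * d), d),
            WV = matrix(rnorm(d * d), d))
  # k = 1: softmax is identically 1, every row equals W_V c
  c1 <- matrix(rnorm(d), 1, d)
  out <- cross_attend(h, c1, w)
  expect_equal(out, matrix(rep(c1 %*% w$WV, each = 5), 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical keys: output is the mean of values regardless of the query
  c3v <- matrix(rnorm(3 * d), 3, d)
  wk_same <- w; wk_same$WK <- matrix(0, d, d)  # all keys equal -> uniform
  out3 <- cross_attend(h, c3v, wk_same)
  expect_equal(out3, matrix(rep(colMeans(c3v %*% w$WV), each = 5), 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # attention rows sum to one
  A <- attr(cross_attend(h, c3v, w), "attention")
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
  expect_error(cross_attend(h, matrix(numeric(), 0, d), w), "no property")
})

test_that("gated fusion is a sigmoid-gated convex combination", {
  withr::local_seed(6)
  h <- matrix(rnorm(12), 4, 3)
  c <- matrix(rnorm(12), 4, 3)
  # zero gate weights give sigma(0) = 0.5
  expect_equal(gated_fuse(h, c, matrix(0, 3, 3)), (h + c) / 2)
  # saturated gate returns h
  expect_equal(gated_fuse(abs(h) + 1, c, diag(3) * 100), abs(h) + 1,
               tolerance = 1e-6)
  # convexity: output bounded between min and max elementwise
  out <- gated_fuse(h, c, matrix(rnorm(9), 3, 3))
  expect_true(all(out >= pmin(h, c) - 1e-12 & out <= pmax(h, c) + 1e-12))
  expect_error(gated_fuse(h, c[1:2, ], matrix(0, 3, 3)), "shape mismatch")
})

test_that("conditioning influences only the value pathway at conditioned layers", {
  den <- tiny_denoiser(seed = 12L)
  sc <- cosine_beta_schedule(60L, 6L)
  cond <- init_conditioner(conditioning_config(model_dim = 16L, heads = 2L,
                                               transformer_layers = 1L,
                                               encode_dim = 8L), seed = 4L)
  X <- matrix(rnorm(15), 5, 3)
  at <- rep("C", 5)
  ctx_a <- encode_properties(cond, list(qed = 0.9))
  ctx_b <- encode_properties(cond, list(mw = 350))
  o_a <- denoiser_forward(den, X, at, 5L, sc, cond = ctx_a)
  o_b <- denoiser_forward(den, X, at, 5L, sc, cond = ctx_b)
  # different targets produce different outputs through the V pathway
  expect_gt(max(abs(o_a$atom_logits - o_b$atom_logits)), 0)
  # zeroing W_V removes all influence of the context value
  den0 <- den
  for (k in names(den0$cond)) den0$cond[[k]]$WV <- 0 * den0$cond[[k]]$WV
  z_a <- denoiser_forward(den0, X, at, 5L, sc, cond = ctx_a)
  z_b <- denoiser_forward(den0, X, at, 5L, sc, cond = ctx_b)
  expect_equal(z_a$atom_logits, z_b$atom_logits, tolerance = 1e-12)
  expect_equal(z_a$eps_coords, z_b$eps_coords, tolerance = 1e-12)
})
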