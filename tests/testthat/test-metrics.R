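test_that("validity, uniqueness and novelty follow counting conventions", {
  train <- c("CCO", "CCN", "CCC")
  # exact copies of training molecules are not novel
  out <- distribution_metrics(c("CCO", "OCC", "NCC"), train)
  expect_equal(out$novelty, 0)
  # 10 molecules, 1 invalid, 9 valid all distinct
  gen <- c("C1CC", "CCO", "CCN", "CCC", "CCCC", "CCCCC", "CCOC", "CCNC",
           "COC", "CNC")
  out2 <- distribution_metrics(gen, train)
  expect_equal(out2$validity, 0.9)
  expect_equal(out2$uniqueness, 1.0)
  # duplicate canonical forms count once
  out3 <- distribution_metrics(c("CCO", "OCC"), train)
  expect_equal(out3$uniqueness, 0.5)
  expect_error(distribution_metrics(character(), train), "empty")
})

test_that("internal diversity and SNN match a brute-force loop", {
  mols <- c("CCO", "CCCN", "c1ccccc1")
  sim <- similarity_metrics(mols, mols)
  fps <- lapply(mols, circular_fp)
  ref_pairs <- c(tanimoto(fps[[1]], fps[[2]]), tanimoto(fps[[1]], fps[[3]]),
                 tanimoto(fps[[2]], fps[[3]]))
  expect_equal(sim$int_div, 1 - mean(ref_pairs), tolerance = 1e-12)
  expect_equal(sim$snn, 1)  # each molecule finds itself in the reference
  # identical molecules: int_div 0
  same <- similarity_metrics(c("CCO", "OCC"), mols)
  expect_equal(same$int_div, 0)
  expect_warning(single <- similarity_metrics("CCO", mols), "singleton")
  expect_equal(single$int_div, 0)
})

test_that("Frechet distance matches closed forms and is symmetric", {
  withr::local_seed(14)
  A <- matrix(rnorm(200), 50, 4)
  expect_equal(frechet_distance(A, A), 0, tolerance = 1e-8)
  # pure mean shift with identical covariance
  d <- c(1, -2, 0.5, 3)
  B <- sweep(A, 2, d, "+")
  expect_equal(frechet_distance(A, B), sum(d^2), tolerance = 1e-8)
  # independent spectral oracle: tr term via eigenvalues of Sa Sb
  C <- matrix(rnorm(200), 50, 4) %*% diag(c(1, 2, 0.5, 1))
  Sa <- cov(A); Sc <- cov(C)
  oracle <- sum((colMeans(A) - colMeans(C))^2) + sum(diag(Sa)) +
    sum(diag(Sc)) - 2 * sum(sqrt(pmax(Re(eigen(Sa %*% Sc)$values), 0)))
  expect_equal(frechet_distance(A, C), oracle, tolerance = 1e-6)
  expect_equal(frechet_distance(A, C), frechet_distance(C, A),
               tolerance = 1e-8)
  expect_error(frechet_distance(A, A[, 1:2]), "dimensionality")
})

test_that("Pareto efficiency counts the rank-1 front", {
  # all points identical: mutual non-dominance of equals
  expect_equal(pareto_efficiency(matrix(1, 7, 3)), 100)
  # strictly dominated chain of 10
  expect_equal(pareto_efficiency(matrix(rep(1:10, 3), 10, 3)), 10)
  # consistency: the counted set is exactly the rank-1 set
  withr::local_seed(20)
  P <- matrix(runif(90), 30, 3)
  expect_equal(pareto_efficiency(P),
               100 * sum(non_dominated_sort(P) == 1L) / 30)
})

test_that("criteria thresholds are inclusive and jointly required", {
  th <- criteria_thresholds()
  expect_equal(criteria_met(data.frame(qed = 0.75, sa = 3.0, novelty = 0.95),
                            th), 100)
  expect_equal(criteria_met(data.frame(qed = 0.70, sa = 3.5, novelty = 0.90),
                            th), 100)   # boundary counts as met
  expect_equal(criteria_met(data.frame(qed = 0.69, sa = 3.0, novelty = 0.95),
                            th), 0)
  df <- data.frame(qed = c(0.8, 0.6), sa = c(3, 3), novelty = c(0.95, 0.95))
  expect_equal(criteria_met(df, th), 50)
})

test_that("desirability is a zero-absorbing geometric mean below the AM", {
  expect_equal(desirability(c(1, 1, 1)), 1)
  expect_equal(desirability(c(0.25, 1)), 0.5)
  expect_equal(desirability(c(0.9, 0, 0.9)), 0)
  expect_error(desirability(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(30)
  for (i in 1:50) {
    v <- runif(sample(2:5, 1))
    expect_lte(desirability(v), mean(v) + 1e-12)
  }
})

test_that("hypervolume is exact on closed forms and monotone", {
  expect_equal(hypervolume(matrix(c(1, 1, 1), 1), rep(0, 3)), 1)
  expect_equal(hypervolume(rbind(c(1, 0.5), c(0.5, 1)), c(0, 0)), 0.75)
  # dominated points contribute nothing
  expect_equal(hypervolume(rbind(c(1, 1), c(0.5, 0.5)), c(0, 0)), 1)
  # k-step staircase closed form
  for (k in c(1L, 3L, 8L)) {
    st <- gen_closed_form_front("staircase", list(k = k))
    expect_equal(hypervolume(st$points, c(0, 0)), st$hv, tolerance = 1e-12)
  }
  bx <- gen_closed_form_front("box", list(a = 0.3, b = 0.7, c = 2))
  expect_equal(hypervolume(bx$points, rep(0, 3)), bx$hv)
  expect_error(hypervolume(rbind(c(-0.1, 1)), c(0, 0)), "reference")
  # monotonicity: adding a non-dominated point never decreases the volume
  withr::local_seed(40)
  for (i in 1:20) {
    P <- matrix(runif(15), 5, 3)
    hv1 <- hypervolume(P, rep(0, 3))
    hv2 <- hypervolume(rbind(P, runif(3)), rep(0, 3))
    expect_gte(hv2 + 1e-12, hv1)
  }
})

test_that("3D hypervolume agrees with a Monte-Carlo oracle", {
  withr::local_seed(50)
  for (rep in 1:3) {
    P <- matrix(runif(12, 0.2, 1), 4, 3)
    hv <- hypervolume(P, rep(0, 3))
    # independent Monte-Carlo estimate over the bounding box
    hi <- apply(P, 2, max)
    U <- cbind(runif(2e5, 0, hi[1]), runif(2e5, 0, hi[2]),
               runif(2e5, 0, hi[3]))
    inside <- rep(FALSE, 2e5)
    for (i in seq_len(nrow(P))) {
      inside <- inside | (U[, 1] <= P[i, 1] & U[, 2] <= P[i, 2] &
                            U[, 3] <= P[i, 3])
    }
    mc <- mean(inside) * prod(hi)
    expect_equal(hv, mc, tolerance = 0.01 * max(hv, mc))
  }
})

test_that("distribution matching reports KS statistics and correlations", {
  withr::local_seed(60)
  A <- data.frame(qed = runif(40), sa = runif(40, 1, 5),
                  logp = rnorm(40), mw = rnorm(40, 300, 20))
  out <- distribution_match(A, A)
  expect_true(all(out$ks$statistic == 0))
  expect_equal(diag(out$correlation), rep(1, 4), ignore_attr = TRUE)
  expect_equal(out$correlation, t(out$correlation))
  B <- data.frame(x = 1:20, y = -(1:20))
  out2 <- distribution_match(B, B)
  expect_equal(out2$correlation["x", "y"], -1)
  Cc <- data.frame(x = rnorm(10), y = rep(1, 10))
  out3 <- distribution_match(Cc, Cc)
  expect_true(is.na(out3$correlation["x", "y"]))
})

test_that("relative change reproduces the benchmark comparison arithmetic", {
  expect_equal(relative_change(0.860, 0.902), 4.9, tolerance = 0.01 * 4.9)
  expect_equal(relative_change(0.445, 0.312, "lower-better"), 29.9,
               tolerance = 0.01 * 29.9)
  expect_equal(relative_change(0.5, 0.5), 0)
  expect_equal(relative_change(0.731, 0.753), 3.0, tolerance = 0.01)
  expect_equal(relative_change(2.97, 2.89, "lower-better"), 2.7,
               tolerance = 0.01)
  expect_equal(relative_change(1.89, 4.21, mode = "fold"), 2.23,
               tolerance = 0.005)
  expect_equal(relative_change(58.3, 91.3, mode = "fold"), 1.57,
               tolerance = 0.005)
  expect_equal(relative_change(0.1, 0.4, mode = "absolute"), 0.3)
  # independence prediction for four simultaneous targets
  expect_equal(100 * 0.866^4, 56.3, tolerance = 0.05)
  expect_error(relative_change(0, 1), "zero baseline")
})
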