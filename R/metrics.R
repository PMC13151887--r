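#' Distribution-learning metrics: validity, uniqueness, novelty
#'
#' Validity is the fraction of generated records that parse and satisfy the
#' valence rules; uniqueness is the fraction of distinct canonical SMILES
#' among the valid ones; novelty is the fraction of unique valid molecules
#' whose canonical SMILES does not occur in the training set (exact set
#' membership — the batch-level convention, distinct from the continuous
#' fingerprint novelty objective of [novelty_score()]).
#'
#' @param generated Character vector of generated SMILES.
#' @param training Character vector of training SMILES.
#' @return Named list `validity`, `uniqueness`, `novelty` (each in \[0,1\]).
#' @export
distribution_metrics <- function(generated, training) {
  if (!length(generated)) stop("empty generated set")
  valid_can <- character()
  for (s in generated) {
    chk <- check_validity(s)
    if (chk$valid) {
      cs <- canonical_smiles(s)
      if (!is.na(cs)) valid_can <- c(valid_can, cs)
    }
  }
  validity <- length(valid_can) / length(generated)
  uniq <- unique(valid_can)
  uniqueness <- if (length(valid_can)) length(uniq) / length(valid_can) else 0
  train_can <- unique(canonical_smiles(training))
  novelty <- if (length(uniq)) mean(!uniq %in% train_can) else 0
  list(validity = validity, uniqueness = uniqueness, novelty = novelty)
}

#' Fingerprint similarity metrics: internal diversity and SNN
#'
#' Internal diversity is one minus the mean pairwise Tanimoto similarity
#' within the generated set (unordered distinct pairs); SNN is the mean,
#' over generated molecules, of the maximum Tanimoto similarity to the
#' reference set.
#'
#' @param generated,reference Lists of [molecule_graph()] objects or SMILES
#'   character vectors.
#' @return Named list `int_div`, `snn`.
#' @export
similarity_metrics <- function(generated, reference) {
  fg <- fingerprint_index(generated)
  fr <- fingerprint_index(reference)
  n <- nrow(fg)
  if (n < 2L) {
    warning("internal diversity undefined for a singleton set; returning 0")
    int_div <- 0
  } else {
    S <- tanimoto_matrix(fg)
    int_div <- 1 - mean(S[upper.tri(S)])
  }
  snn <- mean(vapply(seq_len(n), function(i) {
    max_tanimoto(fg[i, ], fr)
  }, numeric(1)))
  list(int_div = int_div, snn = snn)
}

# symmetric PSD matrix square root via eigendecomposition
sqrtm_sym <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

#' Frechet distance between two descriptor sets
#'
#' Gaussian-moment Frechet distance
#' \eqn{\|\mu_a-\mu_b\|^2 + Tr(\Sigma_a + \Sigma_b -
#' 2(\Sigma_a\Sigma_b)^{1/2})} over pluggable descriptor vectors (the
#' "FCD-style" metric; the learned-network descriptors of the original FCD
#' are out of scope, but any descriptor matrix can be supplied).
#'
#' @param desc_a,desc_b Numeric matrices (rows = molecules, columns =
#'   descriptor dimensions; at least 2 rows each).
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(desc_a, desc_b) {
  A <- as.matrix(desc_a); B <- as.matrix(desc_b)
  if (ncol(A) != ncol(B)) stop("descriptor dimensionality mismatch")
  stopifnot(nrow(A) >= 2L, nrow(B) >= 2L)
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Sa <- stats::cov(A); Sb <- stats::cov(B)
  ra <- sqrtm_sym(Sa)
  cross <- sqrtm_sym(ra %*% Sb %*% ra)
  fd <- sum((mu_a - mu_b)^2) +
    sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(diag(cross))
  max(0, fd)
}

#' Pareto efficiency of an objective cloud
#'
#' Percentage of points on the rank-1 Pareto frontier, computed with the
#' package's non-dominated sorter (maximization orientation).
#'
#' @param objectives Numeric matrix of objective vectors.
#' @return Percentage in \[0, 100\].
#' @export
pareto_efficiency <- function(objectives) {
  P <- as.matrix(objectives)
  if (nrow(P) == 0L) stop("empty objective set")
  ranks <- non_dominated_sort(P, max_fronts = 1L)
  100 * sum(ranks == 1L, na.rm = TRUE) / nrow(P)
}

#' Criteria thresholds for the all-criteria-met rate
#'
#' @param qed_min,sa_max,novelty_min Inclusive thresholds (defaults 0.70,
#'   3.5, 0.90).
#' @return Object of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(qed_min = 0.70, sa_max = 3.5,
                                novelty_min = 0.90) {
  structure(list(qed_min = qed_min, sa_max = sa_max,
                 novelty_min = novelty_min), class = "criteria_thresholds")
}

#' Percentage of molecules meeting all property thresholds
#'
#' A molecule counts when `qed >= qed_min`, `sa <= sa_max` and
#' `novelty >= novelty_min` simultaneously (boundary values count as met).
#'
#' @param records Data frame or matrix with columns `qed`, `sa`, `novelty`.
#' @param th A [criteria_thresholds()].
#' @return Percentage in \[0, 100\].
#' @export
criteria_met <- function(records, th = criteria_thresholds()) {
  r <- as.data.frame(records)
  met <- r$qed >= th$qed_min & r$sa <= th$sa_max & r$novelty >= th$novelty_min
  100 * mean(met)
}

#' Desirability score (geometric mean of normalized objectives)
#'
#' @param values Numeric vector of objective values normalized to \[0,1\].
#' @return Geometric mean in \[0,1\]; zero if any component is zero.
#' @export
desirability <- function(values) {
  if (any(values < 0) || any(values > 1)) {
    stop("desirability components must lie in [0, 1]")
  }
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

#' Normalize (qed, sa, novelty) objectives to \[0,1\] for desirability
#'
#' QED and novelty are already native \[0,1\]; SA is mapped from its
#' \[1,10\] scale and inverted so that easier synthesis scores higher.
#'
#' @param qed,sa,novelty Numeric vectors.
#' @return Matrix with columns `qed`, `sa`, `novelty` in \[0,1\].
#' @export
normalize_objectives <- function(qed, sa, novelty) {
  cbind(qed = pmin(1, pmax(0, qed)),
        sa = pmin(1, pmax(0, (10 - sa) / 9)),
        novelty = pmin(1, pmax(0, novelty)))
}

# exact hypervolume in 2D: staircase sweep over points sorted by x descending
hv_2d <- function(P) {
  ord <- order(-P[, 1L])
  area <- 0
  ymax <- 0
  for (i in ord) {
    if (P[i, 2L] > ymax) {
      area <- area + P[i, 1L] * (P[i, 2L] - ymax)
      ymax <- P[i, 2L]
    }
  }
  area
}

#' Hypervolume dominated by a point set
#'
#' Lebesgue measure of the union of boxes spanned between the reference
#' point and each solution (maximization).  Exact for up to three
#' objectives (slab sweep over the third coordinate); higher dimensions use
#' Monte-Carlo estimation.  Dominated points contribute nothing.
#'
#' @param front Numeric matrix of objective vectors weakly dominating `ref`.
#' @param ref Reference point (defaults to the origin).
#' @param mc_samples Monte-Carlo sample count for more than 3 objectives.
#' @return Non-negative scalar.
#' @export
hypervolume <- function(front, ref = NULL, mc_samples = 1e5) {
  P <- as.matrix(front)
  m <- ncol(P)
  if (is.null(ref)) ref <- rep(0, m)
  if (any(sweep(P, 2L, ref) < 0)) {
    stop("every point must weakly dominate the reference point")
  }
  P <- sweep(P, 2L, ref)
  if (m == 1L) return(max(P))
  if (m == 2L) return(hv_2d(P))
  if (m == 3L) {
    zs <- sort(unique(P[, 3L]), decreasing = TRUE)
    zs <- c(zs, 0)
    vol <- 0
    for (k in seq_len(length(zs) - 1L)) {
      keep <- P[, 3L] >= zs[k]
      vol <- vol + hv_2d(P[keep, 1:2, drop = FALSE]) * (zs[k] - zs[k + 1L])
    }
    return(vol)
  }
  # Monte-Carlo fallback for > 3 objectives
  hi <- apply(P, 2L, max)
  U <- matrix(runif(mc_samples * m), mc_samples, m)
  U <- sweep(U, 2L, hi, "*")
  inside <- rep(FALSE, mc_samples)
  for (i in seq_len(nrow(P))) {
    inside <- inside | rowSums(sweep(U, 2L, P[i, ], "<=") ) == m
  }
  mean(inside) * prod(hi)
}

#' Distribution matching: KS tests and property correlations
#'
#' Two-sample Kolmogorov-Smirnov test per shared continuous property plus
#' the Pearson correlation matrix of the first sample's properties.
#' Constant columns yield `NA` correlations (reported as missing).
#'
#' @param sample_a,sample_b Data frames or matrices with identical column
#'   names (at least 2 rows each).
#' @return List with `ks` (data frame: property, statistic, p_value) and
#'   `correlation` (matrix).
#' @export
distribution_match <- function(sample_a, sample_b) {
  A <- as.data.frame(sample_a); B <- as.data.frame(sample_b)
  props <- intersect(names(A), names(B))
  stopifnot(length(props) >= 1L, nrow(A) >= 2L, nrow(B) >= 2L)
  ks <- do.call(rbind, lapply(props, function(p) {
    kt <- suppressWarnings(stats::ks.test(A[[p]], B[[p]]))
    data.frame(property = p, statistic = unname(kt$statistic),
               p_value = kt$p.value)
  }))
  sds <- vapply(A[props], stats::sd, numeric(1))
  corr <- suppressWarnings(stats::cor(A[props]))
  corr[sds == 0, ] <- NA
  corr[, sds == 0] <- NA
  diag(corr) <- ifelse(sds == 0, NA, 1)
  list(ks = ks, correlation = corr)
}

#' Relative change, absolute change, or fold change
#'
#' `relative` reports `(new - baseline)/baseline` as a percentage, with the
#' sign flipped for lower-is-better quantities so that an improvement is
#' always positive; `absolute` is the raw difference; `fold` is the ratio.
#'
#' @param baseline,new Scalar values.
#' @param direction `"higher-better"` or `"lower-better"`.
#' @param mode `"relative"`, `"absolute"`, or `"fold"`.
#' @return Scalar (percent for `relative`).
#' @export
relative_change <- function(baseline, new,
                            direction = c("higher-better", "lower-better"),
                            mode = c("relative", "absolute", "fold")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (mode %in% c("relative", "fold") && baseline == 0) {
    stop("zero baseline in ", mode, " mode")
  }
  if (mode == "absolute") return(new - baseline)
  if (mode == "fold") return(new / baseline)
  pct <- 100 * (new - baseline) / baseline
  if (direction == "lower-better") pct <- -pct
  pct
}
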