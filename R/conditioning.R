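#' @name conditioning
#' @title Property encoding and cross-attention conditioning
#'
#' @description
#' Target properties are turned into a `k x 256` context matrix that the
#' denoiser attends to.  Continuous properties (QED, SA, logP, MW) are
#' z-scored against training-corpus statistics and passed through a
#' sinusoidal positional encoding (the encoding is scale-sensitive, hence
#' the standardization); discrete properties (ring count, aromatic rings,
#' HBD, HBA) use learned embedding tables over their vocabularies.  Each
#' 64-dim encoding is projected to 256 and tagged with a learned per-property
#' type embedding — there is no positional encoding across property tokens,
#' so the encoder is insensitive to the order in which targets are supplied.
#' A 4-layer, 8-head self-attention encoder produces the final context; a
#' learned null token expresses unconditioned generation through the same
#' forward pass.
NULL

CONT_PROPS <- c("qed", "sa", "logp", "mw")
DISC_VOCAB <- list(ring_count = 0:6, aromatic_rings = 0:4,
                   hbd = 0:5, hba = 0:10)
PROPERTY_ORDER <- c(CONT_PROPS, names(DISC_VOCAB))

#' Sinusoidal encoding of a scalar property value
#'
#' Interleaved sine/cosine encoding
#' \eqn{PE(p, 2i) = \sin(p / 10000^{2i/d})},
#' \eqn{PE(p, 2i+1) = \cos(p / 10000^{2i/d})}.
#'
#' @param p Scalar value.
#' @param d Even encoding dimension (default 64).
#' @return Numeric vector of length `d`.
#' @export
sinusoidal_encode <- function(p, d = 64L) {
  stopifnot(d %% 2L == 0L)
  i <- seq_len(d / 2L) - 1L
  freq <- 1 / 10000^(2 * i / d)
  v <- numeric(d)
  v[2L * i + 1L] <- sin(p * freq)
  v[2L * i + 2L] <- cos(p * freq)
  v
}

#' Conditioning configuration
#'
#' @param encode_dim Per-property encoding dimension (default 64).
#' @param model_dim Context/model dimension (default 256; also the attention
#'   key dimension).
#' @param transformer_layers Self-attention encoder depth (default 4).
#' @param heads Attention heads (default 8).
#' @param tolerance Relative tolerance for target-achievement checks
#'   (default 0.05, i.e. within 5 percent).
#' @return Object of class `conditioning_config`.
#' @export
conditioning_config <- function(encode_dim = 64L, model_dim = 256L,
                                transformer_layers = 4L, heads = 8L,
                                tolerance = 0.05) {
  stopifnot(model_dim %% heads == 0L)
  structure(list(encode_dim = as.integer(encode_dim),
                 model_dim = as.integer(model_dim),
                 transformer_layers = as.integer(transformer_layers),
                 heads = as.integer(heads), d_k = as.integer(model_dim),
                 tolerance = tolerance),
            class = "conditioning_config")
}

# default corpus statistics for z-scoring continuous targets; replaced by
# estimates from the training corpus when a model is trained
default_norm_stats <- function() {
  list(mean = c(qed = 0.5, sa = 3, logp = 2.5, mw = 300),
       sd = c(qed = 0.2, sa = 1, logp = 1.5, mw = 100))
}

#' Initialize conditioner parameters
#'
#' @param config A [conditioning_config()].
#' @param seed Integer seed.
#' @param norm_stats Optional list with `mean` and `sd` named vectors for the
#'   continuous properties.
#' @return Parameter list with the config attached.
#' @export
init_conditioner <- function(config = conditioning_config(), seed = 1L,
                             norm_stats = NULL) {
  with_seed(seed, {
    M <- config$model_dim
    E <- config$encode_dim
    hd <- M %/% config$heads
    tables <- lapply(DISC_VOCAB, function(v) rmat(length(v), E, 0.5))
    type_embed <- rmat(length(PROPERTY_ORDER), M, 0.5)
    rownames(type_embed) <- PROPERTY_ORDER
    tf <- lapply(seq_len(config$transformer_layers), function(l) {
      list(WQ = lapply(seq_len(config$heads), function(h) rmat(M, hd)),
           WK = lapply(seq_len(config$heads), function(h) rmat(M, hd)),
           WV = lapply(seq_len(config$heads), function(h) rmat(M, hd)),
           WO = rmat(M, M),
           W1 = rmat(M, 2L * M), b1 = matrix(0, 1, 2L * M),
           W2 = rmat(2L * M, M), b2 = matrix(0, 1, M))
    })
    list(config = config,
         tables = tables,
         proj = rmat(E, M),
         type_embed = type_embed,
         null_token = rmat(1, M, 0.5),
         tf = tf,
         norm_stats = if (is.null(norm_stats)) default_norm_stats()
                      else norm_stats)
  })
}

#' Discrete-property embedding lookup
#'
#' @param cond Conditioner parameters from [init_conditioner()].
#' @param prop_name One of `ring_count`, `aromatic_rings`, `hbd`, `hba`.
#' @param value Integer value; out-of-vocabulary input is clamped with a
#'   warning.
#' @return Numeric vector of length `encode_dim`.
#' @export
embed_discrete <- function(cond, prop_name, value) {
  if (!prop_name %in% names(DISC_VOCAB)) {
    stop("unknown discrete property '", prop_name, "'")
  }
  vocab <- DISC_VOCAB[[prop_name]]
  if (value < min(vocab) || value > max(vocab)) {
    warning(sprintf("%s=%d outside vocabulary [%d,%d]; clamped",
                    prop_name, value, min(vocab), max(vocab)))
    value <- min(max(vocab), max(min(vocab), value))
  }
  as.numeric(cond$tables[[prop_name]][match(value, vocab), ])
}

# transformer encoder over k x M tokens on an AD tape (no positional
# encoding; residual attention + SiLU feed-forward, no layer norm at this
# scale)
conditioner_encode_ad <- function(P, config, tok, tape) {
  M <- config$model_dim
  for (l in seq_len(config$transformer_layers)) {
    L <- P$tf[[l]]
    heads <- lapply(seq_len(config$heads), function(h) {
      Q <- ad_matmul(tok, L$WQ[[h]])
      K <- ad_matmul(tok, L$WK[[h]])
      V <- ad_matmul(tok, L$WV[[h]])
      A <- ad_softmax_rows(ad_scale(ad_matmul(Q, ad_t(K)),
                                    1 / sqrt(ncol(ad_val(Q)))))
      ad_matmul(A, V)
    })
    tok <- ad_add(tok, ad_matmul(ad_cbind(heads), L$WO))
    ff <- ad_matmul(ad_silu(ad_add(ad_matmul(tok, L$W1), L$b1)), L$W2)
    tok <- ad_add(tok, ad_add(ff, L$b2))
  }
  tok
}

# build the k x M token matrix (numeric) for a named target list
conditioning_tokens <- function(cond, targets) {
  cfg <- cond$config
  if (is.null(targets) || !length(targets)) {
    return(structure(cond$null_token, props = "null"))
  }
  nms <- names(targets)
  bad <- setdiff(nms, PROPERTY_ORDER)
  if (length(bad)) stop("unknown property '", bad[1L], "'")
  ord <- PROPERTY_ORDER[PROPERTY_ORDER %in% nms]
  rows <- t(vapply(ord, function(p) {
    if (p %in% CONT_PROPS) {
      z <- (targets[[p]] - cond$norm_stats$mean[[p]]) / cond$norm_stats$sd[[p]]
      enc <- sinusoidal_encode(z, cfg$encode_dim)
    } else {
      enc <- embed_discrete(cond, p, targets[[p]])
    }
    as.numeric(enc %*% cond$proj) + cond$type_embed[p, ]
  }, numeric(cfg$model_dim)))
  structure(rows, props = ord)
}

#' Encode target properties into a context matrix
#'
#' @param cond Conditioner parameters from [init_conditioner()].
#' @param targets Named list of target values (e.g. `list(qed = 0.8,
#'   mw = 350)`); NULL or empty for the unconditioned null token.
#' @return `k x model_dim` numeric context matrix `c_out`, with the
#'   property order as attribute `"props"` (rows follow the package's fixed
#'   property ordering, independent of input order).
#' @export
encode_properties <- function(cond, targets = NULL) {
  if (!is.null(targets) && length(targets) == 0L) {
    stop("empty target set; pass NULL for unconditioned encoding")
  }
  tok <- conditioning_tokens(cond, targets)
  tape <- ad_tape()
  wrapped <- ad_wrap_params(tape, cond[c("tf")])
  out <- conditioner_encode_ad(wrapped$nodes, cond$config,
                               ad_const(tape, unclass(tok)), tape)
  structure(ad_val(out), props = attr(tok, "props"))
}

# ---- cross-attention and gated fusion -------------------------------------

ad_cross_attend <- function(h, c_out, w) {
  Q <- ad_matmul(h, w$WQ)
  K <- ad_matmul(c_out, w$WK)
  V <- ad_matmul(c_out, w$WV)
  A <- ad_softmax_rows(ad_scale(ad_matmul(Q, ad_t(K)),
                                1 / sqrt(ncol(ad_val(K)))))
  ad_matmul(A, V)
}

ad_gated_fuse <- function(h, c, Wg) {
  g <- ad_sigmoid(ad_matmul(h, Wg))
  ad_add(ad_emul(g, h), ad_emul(ad_add(ad_scale(g, -1), 1), c))
}

#' Cross-attention from node features to property tokens
#'
#' \eqn{Attention(Q, K, V) = softmax(QK^T/\sqrt{d_k}) V} with
#' \eqn{Q = W_Q h}, \eqn{K = W_K c_{out}}, \eqn{V = W_V c_{out}}; each node
#' attends over the `k` property tokens.
#'
#' @param h n x d node feature matrix.
#' @param c_out k x m context matrix.
#' @param weights List with `WQ` (d x d_k), `WK`, `WV` (m x d_k).
#' @return n x d_k attended context (attribute `"attention"` carries the
#'   n x k attention weights).
#' @export
cross_attend <- function(h, c_out, weights) {
  if (nrow(c_out) == 0L) stop("no property tokens to attend to")
  Q <- h %*% weights$WQ
  K <- c_out %*% weights$WK
  V <- c_out %*% weights$WV
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1L, max)
  A <- exp(S) / rowSums(exp(S))
  structure(A %*% V, attention = A)
}

#' Gated fusion of node features with attended context
#'
#' \eqn{h' = \sigma(W_g h) \odot h + (1 - \sigma(W_g h)) \odot c}: an
#' elementwise convex combination whose gate is computed from the node
#' features alone.
#'
#' @param h,c Matrices of identical shape.
#' @param Wg Gate weight matrix (d x d).
#' @return Fused feature matrix.
#' @export
gated_fuse <- function(h, c, Wg) {
  if (!all(dim(h) == dim(c))) stop("shape mismatch between h and c")
  g <- 1 / (1 + exp(-(h %*% Wg)))
  g * h + (1 - g) * c
}

#' Check achieved properties against targets
#'
#' @param achieved Named numeric vector of achieved property values.
#' @param targets Named list of targets.
#' @param tolerance Relative tolerance (default 0.05).
#' @return Named logical vector: within +/- tolerance of each target.
#' @export
target_within_tolerance <- function(achieved, targets, tolerance = 0.05) {
  vapply(names(targets), function(p) {
    tv <- targets[[p]]
    av <- achieved[[p]]
    if (is.null(av) || is.na(av)) return(NA)
    if (tv == 0) abs(av) <= tolerance else abs(av - tv) <= tolerance * abs(tv)
  }, logical(1))
}
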