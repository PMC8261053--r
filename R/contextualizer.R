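#' Transformer contextualizer configuration
#'
#' A standard transformer encoder with all internal normalization layers
#' removed (T-Fixup initialization makes them unnecessary), GELU
#' activations, an additive grouped-convolution position encoder, and a
#' fixed start token prepended to the BENDR sequence. BENDR vectors are
#' bridged to the model dimension by a learned linear up-projection and
#' back down by a learned down-projection, so the contrastive loss and
#' classification heads both operate in BENDR space.
#'
#' @param layers,heads,d_model,d_ff Transformer shape (defaults 8, 8,
#'   1536, 3076).
#' @param layerdrop_p Per-layer skip probability during pre-training.
#' @param dropout_p Dropout probability during pre-training.
#' @param position_rf,position_groups Receptive field and group count of
#'   the convolutional position encoder.
#' @param start_token_value Fill value of the prepended start token,
#'   deliberately outside the harmonized signal range `[-1, 1]`.
#' @param bendr_dim Dimension of the incoming BENDR vectors.
#' @param tfixup_scale Scale applied to value-projection, attention
#'   output and feed-forward weights; default `0.67 * layers^(-1/4)`.
#' @return A `contextualizer_config` list.
#' @export
contextualizer_config <- function(layers = 8L, heads = 8L, d_model = 1536L,
                                  d_ff = 3076L, layerdrop_p = 0.01,
                                  dropout_p = 0.15, position_rf = 25L,
                                  position_groups = 16L,
                                  start_token_value = -5,
                                  bendr_dim = 512L,
                                  tfixup_scale = NULL) {
  stopifnot(d_model %% heads == 0L, d_model %% position_groups == 0L,
            layerdrop_p >= 0, layerdrop_p <= 1, dropout_p >= 0, dropout_p < 1,
            position_rf %% 2L == 1L)
  if (is.null(tfixup_scale)) tfixup_scale <- 0.67 * layers^(-0.25)
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 layerdrop_p = layerdrop_p, dropout_p = dropout_p,
                 position_rf = as.integer(position_rf),
                 position_groups = as.integer(position_groups),
                 start_token_value = start_token_value,
                 bendr_dim = as.integer(bendr_dim),
                 tfixup_scale = tfixup_scale),
            class = "contextualizer_config")
}

.xavier <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' T-Fixup weight initialization for the contextualizer
#'
#' Xavier baseline for all projections, then value-projection, attention
#' output and feed-forward weights in each layer are scaled by
#' `0.67 * N^(-1/4)` (N = layer count). No normalization parameters
#' exist anywhere in the tree. Deterministic under `seed`.
#'
#' @param cfg A `contextualizer_config`.
#' @param seed Integer seed.
#' @return Parameter tree with `in_proj`, `pos_conv`, `layers`,
#'   `out_proj`, `mask_vector`.
#' @export
init_tfixup <- function(cfg, seed = 1L) {
  set.seed(seed)
  d <- cfg$d_model; ff <- cfg$d_ff; s <- cfg$tfixup_scale
  K <- cfg$position_rf; G <- cfg$position_groups; gs <- d %/% G
  layers <- lapply(seq_len(cfg$layers), function(l) {
    list(Wq = .xavier(d, d), bq = numeric(d),
         Wk = .xavier(d, d), bk = numeric(d),
         Wv = .xavier(d, d) * s, bv = numeric(d),
         Wo = .xavier(d, d) * s, bo = numeric(d),
         W1 = .xavier(d, ff) * s, b1 = numeric(ff),
         W2 = .xavier(ff, d) * s, b2 = numeric(d))
  })
  pos_W <- array(stats::rnorm(K * gs * gs * G, sd = sqrt(2 / (K * gs))),
                 dim = c(K, gs, gs, G))
  list(in_proj = list(W = .xavier(cfg$bendr_dim, d), b = numeric(d)),
       pos_conv = list(W = pos_W, b = numeric(d)),
       layers = layers,
       out_proj = list(W = .xavier(d, cfg$bendr_dim), b = numeric(cfg$bendr_dim)),
       mask_vector = stats::rnorm(cfg$bendr_dim, sd = 0.1))
}

#' Replace masked BENDR positions with the learned mask vector
#'
#' Pure function: the input is not modified, and callers retain the
#' original sequence as the contrastive target.
#'
#' @param b L x bendr_dim matrix (or `bendr_sequence`).
#' @param plan A `mask_plan` (see [sample_mask_plan()]).
#' @param m Mask vector of length bendr_dim.
#' @return Masked copy of `b` as a matrix.
#' @export
apply_mask <- function(b, plan, m) {
  if (inherits(b, "bendr_sequence")) b <- b$vectors
  if (length(plan$mask_bool) != nrow(b)) {
    stop("mask plan length does not match sequence length")
  }
  if (any(plan$starts > nrow(b)) || any(plan$starts < 1L)) {
    stop("mask plan positions out of range")
  }
  q <- b
  if (any(plan$mask_bool)) {
    q[plan$mask_bool, ] <- matrix(m, sum(plan$mask_bool), length(m),
                                  byrow = TRUE)
  }
  q
}

#' Prepend the fixed start token
#'
#' Adds a constant vector (default fill -5, outside the harmonized
#' signal range) as position 1; all other positions shift by one. The
#' start position is never maskable and its transformer output is the
#' classification feature.
#'
#' @param b L x bendr_dim matrix (or `bendr_sequence`).
#' @param cfg A `contextualizer_config`.
#' @return (L+1) x bendr_dim matrix.
#' @export
prepend_start_token <- function(b, cfg) {
  if (inherits(b, "bendr_sequence")) b <- b$vectors
  rbind(rep(cfg$start_token_value, ncol(b)), b)
}

# ---- position encoder ------------------------------------------------

pos_encode_fwd <- function(x, p, cfg, keep_cache = FALSE) {
  L <- nrow(x); d <- ncol(x)
  K <- cfg$position_rf; G <- cfg$position_groups; gs <- d %/% G
  pad <- (K - 1L) %/% 2L
  xp <- rbind(matrix(0, pad, d), x, matrix(0, pad, d))
  pre <- matrix(p$b, L, d, byrow = TRUE)
  for (g in seq_len(G)) {
    gc <- ((g - 1L) * gs + 1L):(g * gs)
    xg <- xp[, gc, drop = FALSE]
    acc <- matrix(0, L, gs)
    for (k in seq_len(K)) {
      acc <- acc + xg[k:(k + L - 1L), , drop = FALSE] %*% p$W[k, , , g]
    }
    pre[, gc] <- pre[, gc] + acc
  }
  act <- gelu_fwd(pre)
  y <- x + act$y
  list(y = y,
       cache = if (keep_cache) list(xp = xp, pre = pre, u = act$u, xx = act$xx) else NULL)
}

pos_encode_bwd <- function(dy, cache, p, cfg) {
  L <- nrow(dy); d <- ncol(dy)
  K <- cfg$position_rf; G <- cfg$position_groups; gs <- d %/% G
  pad <- (K - 1L) %/% 2L
  dpre <- gelu_bwd(dy, cache$pre, cache$u, cache$xx)
  dW <- array(0, dim = dim(p$W))
  dxp <- matrix(0, nrow(cache$xp), d)
  for (g in seq_len(G)) {
    gc <- ((g - 1L) * gs + 1L):(g * gs)
    xg <- cache$xp[, gc, drop = FALSE]
    dg <- dpre[, gc, drop = FALSE]
    for (k in seq_len(K)) {
      rows <- k:(k + L - 1L)
      dW[k, , , g] <- crossprod(xg[rows, , drop = FALSE], dg)
      dxp[rows, gc] <- dxp[rows, gc] + dg %*% t(p$W[k, , , g])
    }
  }
  dx <- dy + dxp[(pad + 1L):(pad + L), , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dpre))
}

# ---- transformer layer ----------------------------------------------

.dropout_mask <- function(L, d, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(L * d, 1L, 1 - p) / (1 - p), L, d)
}

attn_layer_fwd <- function(x, p, cfg, train = FALSE, keep_cache = FALSE) {
  if (train && cfg$layerdrop_p > 0 && stats::runif(1) < cfg$layerdrop_p) {
    return(list(y = x, cache = list(skipped = TRUE)))
  }
  L <- nrow(x); d <- cfg$d_model; h <- cfg$heads; dk <- d %/% h
  Q <- linear_fwd(x, p$Wq, p$bq)
  K <- linear_fwd(x, p$Wk, p$bk)
  V <- linear_fwd(x, p$Wv, p$bv)
  A_list <- vector("list", h)
  O <- matrix(0, L, d)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    if (keep_cache) A_list[[i]] <- A
  }
  M <- linear_fwd(O, p$Wo, p$bo)
  dm1 <- if (train) .dropout_mask(L, d, cfg$dropout_p) else NULL
  if (!is.null(dm1)) M <- M * dm1
  x1 <- x + M
  pre1 <- linear_fwd(x1, p$W1, p$b1)
  actf <- gelu_fwd(pre1)
  H <- actf$y
  Fo <- linear_fwd(H, p$W2, p$b2)
  dm2 <- if (train) .dropout_mask(L, d, cfg$dropout_p) else NULL
  if (!is.null(dm2)) Fo <- Fo * dm2
  y <- x1 + Fo
  cache <- if (keep_cache) {
    list(skipped = FALSE, x = x, Q = Q, K = K, V = V, A = A_list, O = O,
         x1 = x1, pre1 = pre1, u1 = actf$u, xx1 = actf$xx, H = H, dm1 = dm1, dm2 = dm2)
  } else NULL
  list(y = y, cache = cache)
}

attn_layer_bwd <- function(dy, cache, p, cfg) {
  if (isTRUE(cache$skipped)) {
    return(list(dx = dy, dp = tree_zeros_like(p)))
  }
  d <- cfg$d_model; h <- cfg$heads; dk <- d %/% h
  dFo <- if (!is.null(cache$dm2)) dy * cache$dm2 else dy
  l2 <- linear_bwd(dFo, cache$H, p$W2)
  dpre1 <- gelu_bwd(l2$dx, cache$pre1, cache$u1, cache$xx1)
  l1 <- linear_bwd(dpre1, cache$x1, p$W1)
  dx1 <- dy + l1$dx
  dM <- if (!is.null(cache$dm1)) dx1 * cache$dm1 else dx1
  lo <- linear_bwd(dM, cache$O, p$Wo)
  dO <- lo$dx
  dQ <- matrix(0, nrow(dy), d); dK <- dQ; dV <- dQ
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    A <- cache$A[[i]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dk)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  lq <- linear_bwd(dQ, cache$x, p$Wq)
  lk <- linear_bwd(dK, cache$x, p$Wk)
  lv <- linear_bwd(dV, cache$x, p$Wv)
  dx <- dx1 + lq$dx + lk$dx + lv$dx
  list(dx = dx,
       dp = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                 Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db,
                 W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

#' Contextualizer forward pass
#'
#' Up-projects a (masked) start-token-prepended BENDR sequence to the
#' model dimension, applies the convolutional position encoder, the
#' transformer layers, and the down-projection back to BENDR space.
#' In train mode LayerDrop and Dropout are active (their randomness
#' comes from R's RNG); in eval mode the pass is deterministic.
#'
#' @param q (L+1) x bendr_dim matrix: masked BENDR with start token.
#' @param params Tree from [init_tfixup()].
#' @param cfg A `contextualizer_config`.
#' @param train Enable stochastic regularizers.
#' @param keep_cache Keep intermediates for [contextualize_backward()].
#' @return List: `start_out` (bendr_dim vector), `sequence_out`
#'   (L x bendr_dim), and `cache`.
#' @export
contextualize <- function(q, params, cfg, train = FALSE, keep_cache = FALSE) {
  x <- linear_fwd(q, params$in_proj$W, params$in_proj$b)
  pe <- pos_encode_fwd(x, params$pos_conv, cfg, keep_cache)
  h <- pe$y
  layer_caches <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    lf <- attn_layer_fwd(h, params$layers[[l]], cfg, train, keep_cache)
    h <- lf$y
    if (keep_cache) layer_caches[[l]] <- lf$cache
  }
  y <- linear_fwd(h, params$out_proj$W, params$out_proj$b)
  if (!all(is.finite(y))) stop("numerical instability: non-finite contextualizer output")
  cache <- if (keep_cache) {
    list(q = q, x_proj = x, pe_cache = pe$cache, layer_caches = layer_caches,
         h_final = h)
  } else NULL
  list(start_out = y[1L, ], sequence_out = y[-1L, , drop = FALSE],
       cache = cache)
}

#' Contextualizer backward pass
#'
#' @param d_start Gradient w.r.t. `start_out` (or NULL).
#' @param d_seq Gradient w.r.t. `sequence_out` (or NULL).
#' @param cache Cache from `contextualize(..., keep_cache = TRUE)`.
#' @param params,cfg As in [contextualize()].
#' @return List: `dq` ((L+1) x bendr_dim) and `dparams`.
#' @export
contextualize_backward <- function(d_start, d_seq, cache, params, cfg) {
  Lp1 <- nrow(cache$q)
  dy <- matrix(0, Lp1, cfg$bendr_dim)
  if (!is.null(d_start)) dy[1L, ] <- d_start
  if (!is.null(d_seq)) dy[-1L, ] <- d_seq
  lo <- linear_bwd(dy, cache$h_final, params$out_proj$W)
  dh <- lo$dx
  dlayers <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    lb <- attn_layer_bwd(dh, cache$layer_caches[[l]], params$layers[[l]], cfg)
    dh <- lb$dx
    dlayers[[l]] <- lb$dp
  }
  pb <- pos_encode_bwd(dh, cache$pe_cache, params$pos_conv, cfg)
  li <- linear_bwd(pb$dx, cache$q, params$in_proj$W)
  list(dq = li$dx,
       dparams = list(in_proj = list(W = li$dW, b = li$db),
                      pos_conv = list(W = pb$dW, b = pb$db),
                      layers = dlayers,
                      out_proj = list(W = lo$dW, b = lo$db),
                      mask_vector = numeric(cfg$bendr_dim)))
}
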