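#' Convolutional encoder configuration
#'
#' Six strided 1D convolution blocks (conv, GroupNorm, GELU) whose
#' kernel lengths equal their strides, so receptive fields tile the
#' input without overlap. The default configuration downsamples by a
#' factor of 96: one output vector summarizes 96 input samples (375 ms
#' at 256 Hz, an effective rate of about 2.67 Hz).
#'
#' @param in_channels Input channel count (20: 19 electrodes + amplitude).
#' @param filters Feature dimension of every block's output.
#' @param kernels Kernel length per block; strides are identical.
#' @param norm_groups GroupNorm group count (must divide `filters`).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(in_channels = 20L, filters = 512L,
                           kernels = c(3L, 2L, 2L, 2L, 2L, 2L),
                           norm_groups = 16L) {
  stopifnot(filters %% norm_groups == 0L, all(kernels >= 1L))
  structure(list(in_channels = as.integer(in_channels),
                 filters = as.integer(filters),
                 kernels = as.integer(kernels),
                 strides = as.integer(kernels),
                 norm_groups = as.integer(norm_groups)),
            class = "encoder_config")
}

#' Total downsampling factor of the encoder
#' @param cfg An `encoder_config`.
#' @return Product of the strides (96 for the default).
#' @export
downsample_factor <- function(cfg) as.integer(prod(cfg$strides))

#' Output length of the encoder for an input of T samples
#'
#' Successive floor division by each stride (valid convolution with
#' kernel == stride); may return 0, which callers must reject.
#'
#' @param T_samples Input length in samples.
#' @param cfg An `encoder_config`.
#' @return Output sequence length L.
#' @export
output_length <- function(T_samples, cfg = encoder_config()) {
  L <- as.integer(T_samples)
  for (k in cfg$kernels) L <- L %/% k
  L
}

#' Initialize encoder weights
#'
#' Kaiming fan-in scaling for the convolution weights, unit/zero affine
#' GroupNorm parameters.
#'
#' @param cfg An `encoder_config`.
#' @param seed Integer seed (deterministic weights).
#' @return Parameter tree: one list per block with `W`, `b`, `gamma`,
#'   `beta`.
#' @export
encoder_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  c_in <- cfg$in_channels
  params <- vector("list", length(cfg$kernels))
  for (i in seq_along(cfg$kernels)) {
    k <- cfg$kernels[i]
    fan_in <- k * c_in
    params[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * cfg$filters, sd = sqrt(2 / fan_in)),
                 fan_in, cfg$filters),
      b = numeric(cfg$filters),
      gamma = rep(1, cfg$filters),
      beta = numeric(cfg$filters)
    )
    c_in <- cfg$filters
  }
  params
}

# fold k consecutive samples of each channel into one row:
# X (T x C) -> Z (L x k*C), column order (channel-major, offset-minor)
.fold_stride <- function(X, k) {
  L <- nrow(X) %/% k
  C <- ncol(X)
  Z <- matrix(0, L, k * C)
  for (j in seq_len(k)) {
    Z[, seq(j, by = k, length.out = C)] <- X[seq(j, L * k, by = k), , drop = FALSE]
  }
  Z
}

.unfold_stride <- function(dZ, k, T_in) {
  L <- nrow(dZ)
  C <- ncol(dZ) %/% k
  dX <- matrix(0, T_in, C)
  for (j in seq_len(k)) {
    dX[seq(j, L * k, by = k), ] <- dZ[, seq(j, by = k, length.out = C), drop = FALSE]
  }
  dX
}

#' Encoder forward pass
#'
#' @param x Input matrix, T x in_channels (time-major; transpose of a
#'   harmonized sequence's `data`).
#' @param params Tree from [encoder_init()].
#' @param cfg An `encoder_config`.
#' @param keep_cache Keep intermediates for [encoder_backward()].
#' @return List: `out` (L x filters BENDR matrix) and `cache`.
#' @export
encoder_forward <- function(x, params, cfg, keep_cache = FALSE) {
  if (nrow(x) < downsample_factor(cfg)) {
    stop(sprintf("input too short: need at least %d samples",
                 downsample_factor(cfg)))
  }
  cache <- if (keep_cache) vector("list", length(cfg$kernels)) else NULL
  h <- x
  for (i in seq_along(cfg$kernels)) {
    k <- cfg$kernels[i]
    T_in <- nrow(h)
    Z <- .fold_stride(h, k)
    pre <- linear_fwd(Z, params[[i]]$W, params[[i]]$b)
    gn <- groupnorm_fwd(pre, params[[i]]$gamma, params[[i]]$beta,
                        cfg$norm_groups)
    act <- gelu_fwd(gn$y)
    if (keep_cache) {
      cache[[i]] <- list(Z = Z, gn_y = gn$y, gn_u = act$u, gn_xx = act$xx,
                         gn_cache = gn$cache, T_in = T_in)
    }
    h <- act$y
  }
  list(out = h, cache = cache)
}

#' Encoder backward pass
#'
#' @param dout Gradient w.r.t. the encoder output (L x filters).
#' @param cache Cache from `encoder_forward(..., keep_cache = TRUE)`.
#' @param params,cfg As in [encoder_forward()].
#' @return List: `dparams` (tree matching `params`).
#' @export
encoder_backward <- function(dout, cache, params, cfg) {
  dparams <- vector("list", length(cfg$kernels))
  dh <- dout
  for (i in rev(seq_along(cfg$kernels))) {
    cc <- cache[[i]]
    dpre_gn <- gelu_bwd(dh, cc$gn_y, cc$gn_u, cc$gn_xx)
    gb <- groupnorm_bwd(dpre_gn, cc$gn_cache)
    lb <- linear_bwd(gb$dx, cc$Z, params[[i]]$W)
    dparams[[i]] <- list(W = lb$dW, b = lb$db,
                         gamma = gb$dgamma, beta = gb$dbeta)
    if (i > 1L) dh <- .unfold_stride(lb$dx, cfg$kernels[i], cc$T_in)
  }
  list(dparams = dparams)
}

#' Encode a harmonized sequence into a BENDR feature sequence
#'
#' @param seq A `harmonized_sequence` (or a 20 x T matrix).
#' @param params Encoder parameter tree.
#' @param cfg An `encoder_config`.
#' @return A `bendr_sequence`: list with `vectors` (L x filters),
#'   `effective_hz`, and provenance tags.
#' @export
encode <- function(seq, params, cfg = encoder_config()) {
  x <- if (inherits(seq, "harmonized_sequence")) t(seq$data) else t(as.matrix(seq))
  sfreq <- if (inherits(seq, "harmonized_sequence")) seq$sfreq else 256
  out <- encoder_forward(x, params, cfg)$out
  structure(
    list(vectors = out,
         effective_hz = sfreq / downsample_factor(cfg),
         subject_id = if (inherits(seq, "harmonized_sequence")) seq$subject_id else NA,
         dataset_id = if (inherits(seq, "harmonized_sequence")) seq$dataset_id else NA),
    class = "bendr_sequence"
  )
}
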