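# Shared differentiable primitives. Sequences are stored time-major
# (L x channels). Every *_bwd consumes the gradient of the loss w.r.t.
# the forward output and the forward cache, and returns gradients for
# inputs and parameters. No autodiff framework is used; gradients are
# closed-form.

# GELU, tanh approximation (exact to ~1e-3; one transcendental per
# element, and the cached tanh makes the backward pass free of them)
.GELU_C <- sqrt(2 / pi)
.GELU_A <- 0.044715

.GELU_CA <- .GELU_C * .GELU_A

gelu <- function(x) {
  0.5 * x * (1 + tanh(x * (.GELU_C + .GELU_CA * x * x)))
}

gelu_fwd <- function(x) {
  xx <- x * x
  u <- tanh(x * (.GELU_C + .GELU_CA * xx))
  list(y = 0.5 * x * (1 + u), u = u, xx = xx)
}

gelu_bwd <- function(dy, x, u, xx = x * x) {
  dy * (0.5 * (1 + u) +
          (0.5 * x) * ((1 - u * u) * (.GELU_C + 3 * .GELU_CA * xx)))
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

linear_fwd <- function(x, W, b) {
  x %*% W + rep(b, each = nrow(x))
}

linear_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# Group normalization over (time x channels-in-group) for a single
# sequence, with per-channel affine parameters.
groupnorm_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  L <- nrow(x); C <- ncol(x); gs <- C %/% groups
  grp <- rep(seq_len(groups), each = gs)
  n <- L * gs
  mu_g <- as.vector(rowsum(.colSums(x, L, C), grp)) / n
  m2_g <- as.vector(rowsum(.colSums(x * x, L, C), grp)) / n
  inv_g <- 1 / sqrt(pmax(m2_g - mu_g^2, 0) + eps)
  xhat <- (x - rep(mu_g[grp], each = L)) * rep(inv_g[grp], each = L)
  y <- xhat * rep(gamma, each = L) + rep(beta, each = L)
  list(y = y, cache = list(xhat = xhat, inv_std = inv_g,
                           gamma = gamma, groups = groups, gs = gs,
                           grp = grp))
}

groupnorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  L <- nrow(dy); C <- ncol(dy); grp <- cache$grp
  n <- L * cache$gs
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cache$gamma, each = L)
  m1 <- as.vector(rowsum(.colSums(dxhat, L, C), grp)) / n
  m2 <- as.vector(rowsum(.colSums(dxhat * xhat, L, C), grp)) / n
  dx <- rep(cache$inv_std[grp], each = L) *
    (dxhat - rep(m1[grp], each = L) - xhat * rep(m2[grp], each = L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- nested parameter-tree utilities (Adam, checkpoints) -------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(a) tree_map(function(x) { x[] <- 0; x }, a)

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(el) tree_sum(f, el), numeric(1)))
  else f(a)
}

#' Initialize Adam optimizer state for a parameter tree
#' @param params Nested list of numeric arrays.
#' @return Optimizer state (first/second moments and step counter).
#' @export
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

#' One decoupled-weight-decay Adam update
#'
#' @param params,grads Matching parameter/gradient trees.
#' @param state State from [adam_init()].
#' @param lr Learning rate for this step.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr, weight_decay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * (u + weight_decay * p),
                      params, upd)
  list(params = params, state = state)
}
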