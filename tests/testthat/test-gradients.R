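# Analytic gradients of the full pre-training objective checked against
# central finite differences on a miniature model, with deterministic
# mask plan and negatives.

make_grad_fixture <- function() {
  ec <- encoder_config(filters = 16L, norm_groups = 4L)
  cc <- contextualizer_config(layers = 2L, heads = 2L, d_model = 16L,
                              d_ff = 24L, bendr_dim = 16L, layerdrop_p = 0,
                              dropout_p = 0, position_groups = 4L)
  set.seed(5)
  list(ec = ec, cc = cc, m = build_model(ec, cc, seed = 5),
       x = matrix(rnorm(20 * 480), 480, 20),
       plan = list(starts = 2L, span = 2L,
                   mask_bool = c(FALSE, TRUE, TRUE, FALSE, FALSE)),
       negs = list(c(1L, 4L, 5L), c(1L, 4L, 5L)))
}

fixture_loss <- function(fx, enc_p, ctx_p, kappa = 0.1) {
  b <- encoder_forward(fx$x, enc_p, fx$ec)$out
  q2 <- prepend_start_token(apply_mask(b, fx$plan, ctx_p$mask_vector), fx$cc)
  co <- contextualize(q2, ctx_p, fx$cc)
  ts <- which(fx$plan$mask_bool)
  lc <- 0
  for (i in seq_along(ts)) {
    lc <- lc + contrastive_loss(co$sequence_out[ts[i], ],
                                b[c(ts[i], fx$negs[[i]]), ], kappa)
  }
  lc / length(ts) + mean(b^2)
}

fixture_grads <- function(fx, enc_p, ctx_p, kappa = 0.1) {
  ef <- encoder_forward(fx$x, enc_p, fx$ec, keep_cache = TRUE)
  b <- ef$out
  q2 <- prepend_start_token(apply_mask(b, fx$plan, ctx_p$mask_vector), fx$cc)
  co <- contextualize(q2, ctx_p, fx$cc, keep_cache = TRUE)
  ts <- which(fx$plan$mask_bool)
  bl <- contrastive_loss_batch(co$sequence_out[ts, , drop = FALSE], b,
                               cbind(ts, do.call(rbind, fx$negs)), kappa)
  dc_seq <- matrix(0, nrow(b), ncol(b))
  dc_seq[ts, ] <- bl$dC / length(ts)
  db <- bl$db / length(ts) + 2 * b / length(b)
  cb <- contextualize_backward(NULL, dc_seq, co$cache, ctx_p, fx$cc)
  dq <- cb$dq[-1L, , drop = FALSE]
  cb$dparams$mask_vector <- colSums(dq[fx$plan$mask_bool, , drop = FALSE])
  db[!fx$plan$mask_bool, ] <- db[!fx$plan$mask_bool, ] +
    dq[!fx$plan$mask_bool, , drop = FALSE]
  eb <- encoder_backward(db, ef$cache, enc_p, fx$ec)
  list(enc = eb$dparams, ctx = cb$dparams)
}

test_that("contrastive loss gradient matches finite differences", {
  set.seed(9)
  ct <- rnorm(16)
  cands <- matrix(rnorm(21 * 16), 21, 16)
  g <- contrastive_loss(ct, cands, 0.1, grad = TRUE)
  eps <- 1e-6
  for (i in c(1L, 7L, 16L)) {
    cp <- ct; cp[i] <- cp[i] + eps
    cm <- ct; cm[i] <- cm[i] - eps
    num <- (contrastive_loss(cp, cands, 0.1) -
              contrastive_loss(cm, cands, 0.1)) / (2 * eps)
    expect_equal(g$dc[i], num, tolerance = 1e-4)
  }
  for (cell in list(c(1L, 2L), c(5L, 3L), c(21L, 16L))) {
    cp <- cands; cp[cell[1], cell[2]] <- cp[cell[1], cell[2]] + eps
    cm <- cands; cm[cell[1], cell[2]] <- cm[cell[1], cell[2]] - eps
    num <- (contrastive_loss(ct, cp, 0.1) -
              contrastive_loss(ct, cm, 0.1)) / (2 * eps)
    expect_equal(g$dcands[cell[1], cell[2]], num, tolerance = 1e-4)
  }
})

test_that("batched contrastive loss agrees with the per-position reference", {
  set.seed(7)
  b <- matrix(rnorm(30 * 16), 30, 16)
  Cm <- matrix(rnorm(5 * 16), 5, 16)
  I <- t(sapply(1:5, function(i) c(i, sample((1:30)[-i], 20, replace = TRUE))))
  bl <- contrastive_loss_batch(Cm, b, I, 0.1)
  ref_loss <- 0
  ref_db <- matrix(0, 30, 16)
  for (i in 1:5) {
    g <- contrastive_loss(Cm[i, ], b[I[i, ], ], 0.1, grad = TRUE)
    ref_loss <- ref_loss + g$loss
    expect_equal(bl$dC[i, ], g$dc, tolerance = 1e-12)
    for (j in 1:21) ref_db[I[i, j], ] <- ref_db[I[i, j], ] + g$dcands[j, ]
  }
  expect_equal(bl$loss_sum, ref_loss, tolerance = 1e-12)
  expect_equal(bl$db, ref_db, tolerance = 1e-12)
})

test_that("end-to-end parameter gradients match finite differences", {
  fx <- make_grad_fixture()
  g <- fixture_grads(fx, fx$m$enc_params, fx$m$ctx_params)
  eps <- 1e-5
  check <- function(mutate, analytic) {
    pp <- mutate(fx$m, eps); pm <- mutate(fx$m, -eps)
    num <- (fixture_loss(fx, pp$enc_params, pp$ctx_params) -
              fixture_loss(fx, pm$enc_params, pm$ctx_params)) / (2 * eps)
    expect_equal(num, analytic, tolerance = 1e-4)
  }
  check(function(m, e) { m$enc_params[[1]]$W[3, 2] <- m$enc_params[[1]]$W[3, 2] + e; m },
        g$enc[[1]]$W[3, 2])
  check(function(m, e) { m$enc_params[[4]]$gamma[5] <- m$enc_params[[4]]$gamma[5] + e; m },
        g$enc[[4]]$gamma[5])
  check(function(m, e) { m$enc_params[[6]]$b[7] <- m$enc_params[[6]]$b[7] + e; m },
        g$enc[[6]]$b[7])
  check(function(m, e) { m$ctx_params$in_proj$W[2, 3] <- m$ctx_params$in_proj$W[2, 3] + e; m },
        g$ctx$in_proj$W[2, 3])
  check(function(m, e) { m$ctx_params$pos_conv$W[13, 2, 3, 3] <- m$ctx_params$pos_conv$W[13, 2, 3, 3] + e; m },
        g$ctx$pos_conv$W[13, 2, 3, 3])
  check(function(m, e) { m$ctx_params$layers[[1]]$Wq[4, 4] <- m$ctx_params$layers[[1]]$Wq[4, 4] + e; m },
        g$ctx$layers[[1]]$Wq[4, 4])
  check(function(m, e) { m$ctx_params$layers[[1]]$Wv[2, 7] <- m$ctx_params$layers[[1]]$Wv[2, 7] + e; m },
        g$ctx$layers[[1]]$Wv[2, 7])
  check(function(m, e) { m$ctx_params$layers[[2]]$W2[10, 3] <- m$ctx_params$layers[[2]]$W2[10, 3] + e; m },
        g$ctx$layers[[2]]$W2[10, 3])
  check(function(m, e) { m$ctx_params$out_proj$W[5, 6] <- m$ctx_params$out_proj$W[5, 6] + e; m },
        g$ctx$out_proj$W[5, 6])
  check(function(m, e) { m$ctx_params$mask_vector[3] <- m$ctx_params$mask_vector[3] + e; m },
        g$ctx$mask_vector[3])
})
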