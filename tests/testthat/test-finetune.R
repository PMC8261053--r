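test_that("evenly spaced evaluation masks are disjoint and correctly placed", {
  p160 <- evenly_spaced_mask_plan(160, 0.065, 10L)
  expect_equal(p160$N_m, 5L)
  expect_equal(p160$spacing, 32L)
  expect_equal(p160$starts, c(1L, 33L, 65L, 97L, 129L))
  expect_equal(sum(p160$mask_bool), 50L)
  p53 <- evenly_spaced_mask_plan(53, 0.065, 10L)
  expect_equal(p53$N_m, 1L)
  expect_equal(p53$starts, 1L)
  # guard arithmetic: L = 15 still yields one valid span
  p15 <- evenly_spaced_mask_plan(15, 0.065, 10L)
  expect_equal(p15$N_m, 1L)
  expect_error(evenly_spaced_mask_plan(9, 0.065, 10L), "overlap")
  # disjointness across a range of lengths
  for (L in c(53, 80, 120, 160, 320)) {
    pl <- evenly_spaced_mask_plan(L, 0.065, 10L)
    expect_equal(sum(pl$mask_bool), pl$N_m * 10L)
  }
})

test_that("contrastive accuracy counts strict wins only", {
  d <- 8
  b <- diag(1, 4, d)                 # orthogonal rows
  plan <- list(starts = 1L, span = 2L,
               mask_bool = c(TRUE, TRUE, FALSE, FALSE))
  negs <- list(c(3L, 4L), c(3L, 4L))
  # contextual output aligned with the target at both positions
  cseq <- b * 0.9
  expect_equal(contrastive_accuracy(cseq, b, plan, negs), 1)
  # all-equal similarities: ties count as incorrect
  ones <- matrix(1, 4, d)
  expect_equal(contrastive_accuracy(matrix(1, 4, d), ones, plan, negs), 0)
})

test_that("pooling averages four contiguous near-equal parts", {
  d <- 6
  b4 <- matrix(rnorm(4 * d), 4, d)
  expect_equal(pool_bendr(b4), as.vector(t(b4)))
  b8 <- matrix(0, 8, d)
  for (i in 1:8) b8[i, ] <- i
  pooled <- pool_bendr(b8)
  expect_equal(pooled, rep(c(1.5, 3.5, 5.5, 7.5), each = d))
  cst <- matrix(rep(1:d, each = 7), 7, d)
  expect_equal(pool_bendr(cst), rep(1:d, times = 4))
  expect_error(pool_bendr(matrix(0, 3, d)), "too short")
})

test_that("downstream regularizer has the prescribed span arithmetic", {
  set.seed(1)
  b <- matrix(rnorm(53 * 512), 53, 512)
  m <- rnorm(512)
  # zero probabilities: identity
  cfg0 <- downstream_reg_config(span_start_p = 0, feat_start_p = 0)
  expect_identical(downstream_regularize(b, m, cfg0)$b, b)
  # span lengths: round(0.10 * L) = 5 time steps at L = 53 and
  # floor(0.10 * 512) = 51 features; isolated interior runs have
  # exactly these lengths, merged overlaps only ever lengthen them
  cfg <- downstream_reg_config()
  interior_runs <- function(mask) {
    r <- rle(mask)
    pos <- which(r$values)
    r$lengths[r$values][pos > 1 & pos < length(r$values)]
  }
  tlens <- integer(0); flens <- integer(0)
  for (s in 1:400) {
    set.seed(s)
    rg <- downstream_regularize(b, m, cfg)
    tlens <- c(tlens, interior_runs(rg$time_mask))
    flens <- c(flens, interior_runs(rg$feat_mask))
    if (any(rg$time_mask) && !any(rg$feat_mask)) {
      expect_true(all(apply(rg$b[rg$time_mask, , drop = FALSE], 1,
                            function(r) all(r == m))))
    }
    if (any(rg$feat_mask)) expect_true(all(rg$b[, rg$feat_mask] == 0))
  }
  expect_true(all(tlens >= 5L) && any(tlens == 5L))
  expect_true(all(flens >= 51L) && any(flens == 51L))
})

test_that("the six variant specifications match the transfer-learning table", {
  s <- lapply(1:6, finetune_spec)
  expect_equal(vapply(s, `[[`, "", "load_encoder"),
               c("pretrained", "pretrained", "random", "pretrained",
                 "random", "pretrained"))
  expect_equal(vapply(s, `[[`, "", "load_contextualizer"),
               c("pretrained", "absent", "absent", "pretrained", "random",
                 "absent"))
  expect_equal(vapply(s, `[[`, "", "head"),
               c("start_token", "pooled", "pooled", "start_token",
                 "start_token", "pooled"))
  expect_equal(lapply(s, `[[`, "frozen"),
               list(character(0), character(0), character(0), "encoder",
                    character(0), "encoder"))
})

make_tiny_checkpoint <- function() {
  if (is.null(.fix$ckpt)) {
    m <- build_model(tiny_enc_cfg(), tiny_ctx_cfg(), seed = 21)
    path <- tempfile(fileext = ".rds")
    save_checkpoint(m, path)
    .fix$ckpt <- load_checkpoint(path)
  }
  .fix$ckpt
}

test_that("variant assembly enforces checkpoint requirements", {
  ck <- make_tiny_checkpoint()
  expect_error(build_finetune_model(1, NULL, n_classes = 2), "requires")
  expect_error(build_finetune_model(3, ck, n_classes = 2), "scratch")
  m2 <- build_finetune_model(2, ck, n_classes = 2, seed = 3)
  m3 <- build_finetune_model(3, NULL, n_classes = 2,
                             enc_cfg = tiny_enc_cfg(),
                             ctx_cfg = tiny_ctx_cfg(), seed = 3)
  # (2, 3): identical architecture, different weights
  expect_equal(lapply(m2$enc_params, function(b) dim(b$W)),
               lapply(m3$enc_params, function(b) dim(b$W)))
  expect_equal(dim(m2$head$W), dim(m3$head$W))
  expect_gt(tree_max_abs_diff(m2$enc_params, m3$enc_params), 0)
  # (1, 5): identical parameter counts
  m1 <- build_finetune_model(1, ck, n_classes = 2, seed = 3)
  m5 <- build_finetune_model(5, NULL, n_classes = 2,
                             enc_cfg = tiny_enc_cfg(),
                             ctx_cfg = tiny_ctx_cfg(), seed = 3)
  count <- function(m) {
    tree_sum(length, m$enc_params) + tree_sum(length, m$ctx_params) +
      tree_sum(length, m$head)
  }
  expect_equal(count(m1), count(m5))
  # (2, 6): identical initial weights, different trainable sets
  m6 <- build_finetune_model(6, ck, n_classes = 2, seed = 3)
  expect_equal(tree_max_abs_diff(m2$enc_params, m6$enc_params), 0)
  expect_equal(m2$spec$frozen, character(0))
  expect_equal(m6$spec$frozen, "encoder")
})

test_that("frozen sub-trees are bitwise unchanged by training", {
  ck <- make_tiny_checkpoint()
  tr <- fixture_trials(ratio = 3, n_per_class = 6L)
  trials <- harmonize_trials(tr)
  for (v in c(4L, 6L)) {
    m <- build_finetune_model(v, ck, n_classes = 2, seed = 2)
    before <- m$enc_params
    mt <- train_finetune(m, trials, tr$labels,
                         finetune_config(epochs = 2L, batch_size = 4L,
                                         peak_lr = 5e-3, seed = 2L))
    expect_identical(mt$enc_params, before)
    expect_gt(tree_max_abs_diff(mt$head, m$head), 0)
  }
  # and the complement: variant 2 does move the encoder
  m2 <- build_finetune_model(2, ck, n_classes = 2, seed = 2)
  mt2 <- train_finetune(m2, trials, tr$labels,
                        finetune_config(epochs = 1L, batch_size = 4L,
                                        peak_lr = 5e-3, seed = 2L))
  expect_gt(tree_max_abs_diff(mt2$enc_params, m2$enc_params), 0)
})

test_that("per-epoch undersampling balances classes exactly", {
  set.seed(5)
  lab <- c(rep("A", 10), rep("B", 4))
  idx <- undersample_epoch(lab)
  expect_length(idx, 8L)
  expect_equal(as.vector(table(lab[idx])), c(4L, 4L))
  # minority class contributes all its points
  expect_setequal(idx[lab[idx] == "B"], which(lab == "B"))
  lab2 <- rep(c("A", "B"), each = 5)
  expect_setequal(undersample_epoch(lab2), 1:10)
  lab3 <- c(rep("A", 9), rep("B", 6), rep("C", 3))
  idx3 <- undersample_epoch(lab3)
  expect_equal(as.vector(table(lab3[idx3])), c(3L, 3L, 3L))
  expect_error(undersample_epoch(rep("A", 5)), "two classes")
})

test_that("metrics behave on canonical cases", {
  lab <- factor(c("a", "a", "b", "b"))
  expect_equal(metric(c("a", "a", "b", "b"), lab, "BAC"), 1)
  expect_equal(metric(c("a", "a", "b", "b"), lab, "accuracy"), 1)
  expect_equal(metric(rep("a", 4), lab, "BAC"), 0.5)
  sc <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(metric(NULL, lab, "AUROC", scores = sc), 1)
  a1 <- metric(NULL, lab, "AUROC", scores = sc)
  a2 <- metric(NULL, lab, "AUROC", scores = -sc)
  expect_equal(a2, 1 - a1)
  expect_error(metric(c("a", "a"), factor(c("a", "a"), levels = c("a", "b")),
                      "BAC"), "single class")
})

test_that("metric normalization is affine from chance to perfect", {
  expect_equal(normalize_metric(0.5, 0.5), 0)
  expect_equal(normalize_metric(1, 0.5), 1)
  expect_equal(normalize_metric(0.75, 0.5), 0.5)
  expect_equal(normalize_metric(0.25, 0.25), 0)
  expect_lt(normalize_metric(0.4, 0.5), 0)
  v <- seq(0, 1, 0.1)
  expect_true(all(diff(normalize_metric(v, 0.3)) > 0))
})

test_that("fold assignment partitions subjects atomically", {
  ck <- make_tiny_checkpoint()
  tr <- fixture_trials(ratio = 3, n_per_class = 8L)
  trials <- harmonize_trials(tr)
  res <- run_finetune(trials, tr$labels, tr$subjects, variant = 6,
                      checkpoint = ck, n_folds = 2L,
                      cfg = finetune_config(epochs = 1L, batch_size = 8L,
                                            peak_lr = 5e-3),
                      n_boot = 50L, seed = 4L)
  tab <- res$table
  expect_false(any(duplicated(tab$subject)))
  expect_equal(sort(unique(tab$subject)), sort(unique(tr$subjects)))
  by_fold <- split(tab$subject, tab$fold)
  expect_length(intersect(by_fold[[1]], by_fold[[2]]), 0L)
  expect_true(all(c("mean", "ci_lo", "ci_hi") %in% names(res$summary)))
  expect_lte(res$summary$ci_lo, res$summary$mean)
  expect_gte(res$summary$ci_hi, res$summary$mean)
})
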