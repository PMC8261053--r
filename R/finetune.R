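#' Evenly spaced evaluation mask plan
#'
#' The held-out contrastive evaluation masks half the amount expected
#' during training, with spans evenly spaced so none overlap:
#' `N_m = max(1, floor(0.5 * L * p_mask))` spans of `span` steps,
#' spaced `floor(L / N_m)` apart, the first starting at position 1.
#'
#' @param L Sequence length in BENDR steps.
#' @param p_mask Training span-start probability.
#' @param span Span length.
#' @return A `mask_plan` with non-overlapping spans.
#' @export
evenly_spaced_mask_plan <- function(L, p_mask = 0.065, span = 10L) {
  N_m <- max(1L, floor(0.5 * L * p_mask))
  spacing <- L %/% N_m
  if (spacing < span) {
    stop("sequence too short for the evaluation protocol: spans would overlap")
  }
  starts <- 1L + spacing * (seq_len(N_m) - 1L)
  structure(list(starts = starts, span = as.integer(span),
                 mask_bool = .make_mask_bool(starts, span, L),
                 N_m = N_m, spacing = spacing),
            class = "mask_plan")
}

#' Contrastive accuracy over masked positions
#'
#' Fraction of masked positions at which the contextual output is
#' strictly more cosine-similar to the true BENDR vector than to every
#' distractor; ties count as incorrect.
#'
#' @param cseq Contextual sequence output (L x d).
#' @param b Unmasked BENDR matrix (L x d).
#' @param plan A `mask_plan`.
#' @param negatives List of distractor index vectors, one per masked
#'   position (in `which(plan$mask_bool)` order).
#' @return Fraction correct.
#' @export
contrastive_accuracy <- function(cseq, b, plan, negatives) {
  pos <- which(plan$mask_bool)
  stopifnot(length(negatives) == length(pos))
  n_ok <- 0L
  for (i in seq_along(pos)) {
    t <- pos[i]
    cands <- b[c(t, negatives[[i]]), , drop = FALSE]
    ct <- cseq[t, ]
    sims <- as.numeric(cands %*% ct) /
      (sqrt(sum(ct^2)) * sqrt(rowSums(cands^2)))
    if (all(sims[1L] > sims[-1L])) n_ok <- n_ok + 1L
  }
  n_ok / length(pos)
}

#' Evaluate the contrastive task on held-out windows
#'
#' Applies the evenly spaced masking protocol to each window, runs the
#' model in eval mode, and reports per-window accuracy.
#'
#' @param model Model list (`enc_params`, `ctx_params`, configs).
#' @param windows List of `harmonized_sequence` windows.
#' @param cfg A `pretrain_config` (for `p_mask`, `span`, negatives).
#' @param seed Seed for negative sampling (eval determinism).
#' @return Data.frame: subject, window, n_masked, accuracy.
#' @export
eval_contrastive <- function(model, windows, cfg = pretrain_config(),
                             seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    b <- encode(w, model$enc_params, model$enc_cfg)$vectors
    L <- nrow(b)
    plan <- evenly_spaced_mask_plan(L, cfg$p_mask, cfg$span)
    q2 <- prepend_start_token(apply_mask(b, plan, model$ctx_params$mask_vector),
                              model$ctx_cfg)
    co <- contextualize(q2, model$ctx_params, model$ctx_cfg, train = FALSE)
    pos <- which(plan$mask_bool)
    negs <- lapply(pos, function(t) sample_negative_indices(L, t, cfg))
    acc <- contrastive_accuracy(co$sequence_out, b, plan, negs)
    data.frame(subject = as.character(w$subject_id), window = i,
               n_masked = length(pos), accuracy = acc)
  })
  do.call(rbind, rows)
}

#' Contrastive accuracy as evaluation length varies
#'
#' Cuts each harmonized sequence into non-overlapping windows of each
#' requested length and evaluates the contrastive task per length.
#'
#' @param model Model list.
#' @param sequences List of `harmonized_sequence` (held-out subjects).
#' @param lengths_s Window lengths in seconds (e.g. `c(20, 30, 45, 60)`).
#' @param cfg A `pretrain_config`.
#' @param seed Seed for negative sampling.
#' @return Data.frame: subject, length_s, accuracy (mean over windows).
#' @export
length_sweep <- function(model, sequences, lengths_s = c(20, 30, 45, 60),
                         cfg = pretrain_config(), seed = 1L) {
  rows <- list()
  for (len in lengths_s) {
    for (sq in sequences) {
      wins <- window_pretrain(sq, len)
      if (length(wins) == 0L) next
      tab <- eval_contrastive(model, wins, cfg, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = as.character(sq$subject_id), length_s = len,
        accuracy = stats::weighted.mean(tab$accuracy, tab$n_masked))
    }
  }
  do.call(rbind, rows)
}

#' Pooled-BENDR feature vector
#'
#' Splits the BENDR sequence into four contiguous near-equal parts
#' (lengths differing by at most one), averages each, and concatenates
#' the means into a `4 * d` feature vector.
#'
#' @param b L x d BENDR matrix (or `bendr_sequence`), L >= 4.
#' @return Numeric vector of length `4 * d`.
#' @export
pool_bendr <- function(b) {
  if (inherits(b, "bendr_sequence")) b <- b$vectors
  L <- nrow(b)
  if (L < 4L) stop("sequence too short to pool: need L >= 4")
  sizes <- rep(L %/% 4L, 4L)
  if (L %% 4L > 0L) sizes[seq_len(L %% 4L)] <- sizes[seq_len(L %% 4L)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-4L] + 1L)
  unlist(lapply(1:4, function(k) colMeans(b[starts[k]:ends[k], , drop = FALSE])))
}

#' Downstream regularization configuration
#' @param span_frac Time-mask span as a fraction of the sequence.
#' @param span_start_p Per-position probability of starting a time mask.
#' @param feat_frac Feature-dropout span as a fraction of the features.
#' @param feat_start_p Per-feature probability of starting a dropout span.
#' @return A `downstream_reg_config` list.
#' @export
downstream_reg_config <- function(span_frac = 0.10, span_start_p = 0.01,
                                  feat_frac = 0.10, feat_start_p = 0.005) {
  structure(list(span_frac = span_frac, span_start_p = span_start_p,
                 feat_frac = feat_frac, feat_start_p = feat_start_p),
            class = "downstream_reg_config")
}

#' Downstream sequence regularizer
#'
#' Training-time regularization of a trial's BENDR: contiguous time
#' spans of `round(span_frac * L)` steps (minimum 1) are replaced by
#' the pre-training mask vector with start probability `span_start_p`
#' per position, and contiguous feature spans of `floor(feat_frac * d)`
#' features (51 of 512) are zeroed with start probability
#' `feat_start_p` per feature.
#'
#' @param b L x d BENDR matrix.
#' @param m Mask vector (zeros when training from scratch).
#' @param cfg A `downstream_reg_config`.
#' @return List: `b` (regularized), `time_mask` (logical L),
#'   `feat_mask` (logical d, TRUE = dropped).
#' @export
downstream_regularize <- function(b, m, cfg = downstream_reg_config()) {
  L <- nrow(b); d <- ncol(b)
  tspan <- max(1L, as.integer(round(cfg$span_frac * L)))
  tstarts <- which(stats::runif(L) < cfg$span_start_p)
  time_mask <- .make_mask_bool(tstarts, tspan, L)
  fspan <- max(1L, as.integer(floor(cfg$feat_frac * d)))
  fstarts <- which(stats::runif(d) < cfg$feat_start_p)
  feat_mask <- .make_mask_bool(fstarts, fspan, d)
  out <- b
  if (any(time_mask)) out[time_mask, ] <- matrix(m, sum(time_mask), d, byrow = TRUE)
  if (any(feat_mask)) out[, feat_mask] <- 0
  list(b = out, time_mask = time_mask, feat_mask = feat_mask)
}

#' The six transfer-learning configurations
#'
#' 1. pre-trained encoder + pre-trained transformer, start-token head,
#'    everything trainable.
#' 2. pre-trained encoder only, pooled-BENDR linear head.
#' 3. as 2 but randomly initialized (no pre-training).
#' 4. as 1 but the encoder frozen.
#' 5. as 1 but randomly initialized (no pre-training).
#' 6. as 2 but the encoder frozen (train only the head).
#'
#' @param variant Integer 1-6.
#' @return A `finetune_spec` list: `load_encoder`, `load_contextualizer`,
#'   `frozen`, `head`.
#' @export
finetune_spec <- function(variant) {
  stopifnot(variant %in% 1:6)
  tab <- list(
    list(load_encoder = "pretrained", load_contextualizer = "pretrained",
         frozen = character(0), head = "start_token"),
    list(load_encoder = "pretrained", load_contextualizer = "absent",
         frozen = character(0), head = "pooled"),
    list(load_encoder = "random", load_contextualizer = "absent",
         frozen = character(0), head = "pooled"),
    list(load_encoder = "pretrained", load_contextualizer = "pretrained",
         frozen = "encoder", head = "start_token"),
    list(load_encoder = "random", load_contextualizer = "random",
         frozen = character(0), head = "start_token"),
    list(load_encoder = "pretrained", load_contextualizer = "absent",
         frozen = "encoder", head = "pooled")
  )
  structure(c(list(variant = as.integer(variant)), tab[[variant]]),
            class = "finetune_spec")
}

#' Assemble a fine-tuning model for one variant
#'
#' @param variant Integer 1-6.
#' @param checkpoint A checkpoint list from [load_checkpoint()]
#'   (required for variants 1, 2, 4, 6; forbidden for 3 and 5).
#' @param n_classes Number of downstream classes.
#' @param enc_cfg,ctx_cfg Configurations for randomly initialized
#'   variants (taken from the checkpoint otherwise).
#' @param seed Seed for the random head (and random stages).
#' @return A `finetune_model` list.
#' @export
build_finetune_model <- function(variant, checkpoint = NULL, n_classes,
                                 enc_cfg = encoder_config(),
                                 ctx_cfg = contextualizer_config(),
                                 seed = 1L) {
  spec <- finetune_spec(variant)
  needs_ckpt <- spec$load_encoder == "pretrained" ||
    spec$load_contextualizer == "pretrained"
  if (needs_ckpt && is.null(checkpoint)) {
    stop(sprintf("variant %d requires a pre-trained checkpoint", variant))
  }
  if (!needs_ckpt && !is.null(checkpoint)) {
    stop(sprintf("variant %d trains from scratch; do not supply a checkpoint",
                 variant))
  }
  if (!is.null(checkpoint)) {
    enc_cfg <- checkpoint$enc_cfg
    ctx_cfg <- checkpoint$ctx_cfg
  }
  set.seed(seed)
  enc_params <- if (spec$load_encoder == "pretrained") checkpoint$enc_params
                else encoder_init(enc_cfg, seed = seed)
  ctx_params <- switch(spec$load_contextualizer,
    pretrained = checkpoint$ctx_params,
    random = init_tfixup(ctx_cfg, seed = seed + 1L),
    absent = NULL)
  mask_vec <- if (!is.null(checkpoint)) checkpoint$ctx_params$mask_vector
              else numeric(enc_cfg$filters)
  in_dim <- if (spec$head == "start_token") ctx_cfg$bendr_dim
            else 4L * enc_cfg$filters
  set.seed(seed + 2L)
  head <- list(W = .xavier(in_dim, n_classes), b = numeric(n_classes))
  structure(list(spec = spec, enc_params = enc_params,
                 ctx_params = ctx_params, head = head,
                 mask_vector = mask_vec, n_classes = as.integer(n_classes),
                 enc_cfg = enc_cfg, ctx_cfg = ctx_cfg),
            class = "finetune_model")
}

# forward one trial; returns logits and (optionally) caches for backward
.ft_forward <- function(model, trial, train = FALSE, reg_cfg = NULL,
                        keep_cache = FALSE) {
  x <- t(as.matrix(trial))
  ef <- encoder_forward(x, model$enc_params, model$enc_cfg,
                        keep_cache = keep_cache)
  b <- ef$out
  if (train && !is.null(reg_cfg)) {
    rg <- downstream_regularize(b, model$mask_vector, reg_cfg)
  } else {
    rg <- list(b = b, time_mask = logical(nrow(b)),
               feat_mask = logical(ncol(b)))
  }
  if (model$spec$head == "start_token") {
    q2 <- prepend_start_token(rg$b, model$ctx_cfg)
    co <- contextualize(q2, model$ctx_params, model$ctx_cfg,
                        train = FALSE, keep_cache = keep_cache)
    feat <- co$start_out
  } else {
    co <- NULL
    feat <- pool_bendr(rg$b)
  }
  logits <- as.numeric(feat %*% model$head$W) + model$head$b
  list(logits = logits, feat = feat, b = b, rg = rg, ef = ef, co = co)
}

# cross-entropy backward through head, contextualizer/pool, encoder
.ft_backward <- function(model, fwd, dlogits) {
  grads <- list(head = list(W = outer(fwd$feat, dlogits), b = dlogits),
                enc = NULL, ctx = NULL)
  dfeat <- as.numeric(model$head$W %*% dlogits)
  frozen_enc <- "encoder" %in% model$spec$frozen
  if (model$spec$head == "start_token") {
    cb <- contextualize_backward(dfeat, NULL, fwd$co$cache,
                                 model$ctx_params, model$ctx_cfg)
    grads$ctx <- cb$dparams
    db <- cb$dq[-1L, , drop = FALSE]
  } else {
    b <- fwd$rg$b
    L <- nrow(b); d <- ncol(b)
    sizes <- rep(L %/% 4L, 4L)
    if (L %% 4L > 0L) sizes[seq_len(L %% 4L)] <- sizes[seq_len(L %% 4L)] + 1L
    ends <- cumsum(sizes); starts <- c(1L, ends[-4L] + 1L)
    db <- matrix(0, L, d)
    for (k in 1:4) {
      dpart <- dfeat[((k - 1L) * d + 1L):(k * d)] / sizes[k]
      db[starts[k]:ends[k], ] <- matrix(dpart, sizes[k], d, byrow = TRUE)
    }
  }
  if (!frozen_enc) {
    # entries replaced by the regularizer carry no gradient into b
    db[fwd$rg$time_mask, ] <- 0
    db[, fwd$rg$feat_mask] <- 0
    eb <- encoder_backward(db, fwd$ef$cache, model$enc_params, model$enc_cfg)
    grads$enc <- eb$dparams
  }
  grads
}

#' Per-epoch balanced undersampling
#'
#' The least frequent class contributes all of its points; every other
#' class contributes the same number of points, drawn uniformly with
#' replacement, so each epoch sees exactly `n_min` points per class.
#'
#' @param labels Vector of class labels (>= 2 nonempty classes).
#' @return Integer index multiset into `labels`.
#' @export
undersample_epoch <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("undersampling requires at least two classes")
  if (any(tab == 0L)) stop("empty class")
  n_min <- min(tab)
  idx <- integer(0)
  for (cl in names(tab)) {
    members <- which(labels == cl)
    if (length(members) == n_min) idx <- c(idx, members)
    else idx <- c(idx, sample(members, n_min, replace = TRUE))
  }
  idx
}

#' Fine-tuning optimization configuration
#' @param epochs Training epochs.
#' @param batch_size Trials per optimization step.
#' @param peak_lr Peak learning rate.
#' @param weight_decay Decoupled Adam weight decay.
#' @param warmup_frac Warm-up fraction of total steps (0.10 downstream).
#' @param reg A `downstream_reg_config`.
#' @param seed RNG seed.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(epochs = 20L, batch_size = 8L, peak_lr = 5e-5,
                            weight_decay = 0.01, warmup_frac = 0.10,
                            reg = downstream_reg_config(), seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), peak_lr = peak_lr,
                 weight_decay = weight_decay, warmup_frac = warmup_frac,
                 reg = reg, seed = as.integer(seed)),
            class = "finetune_config")
}

#' Train a fine-tuning model
#'
#' Adam with decoupled weight decay and a cosine schedule with linear
#' warm-up; classes are re-balanced by [undersample_epoch()] every
#' epoch; the downstream regularizer is applied in training mode only.
#' Frozen components receive no updates.
#'
#' @param model A `finetune_model`.
#' @param trials List of 20 x T trial matrices.
#' @param labels Class labels (coerced to factor).
#' @param cfg A `finetune_config`.
#' @return The trained model (with a `history` attribute of per-epoch
#'   mean training loss).
#' @export
train_finetune <- function(model, trials, labels, cfg = finetune_config()) {
  set.seed(cfg$seed)
  labels <- factor(labels)
  lab_int <- as.integer(labels)
  stopifnot(nlevels(labels) == model$n_classes)
  n_min <- min(table(labels))
  steps_per_epoch <- max(1L, ceiling(nlevels(labels) * n_min / cfg$batch_size))
  sched <- list(peak_lr = cfg$peak_lr, warmup_frac = cfg$warmup_frac,
                total_steps = cfg$epochs * steps_per_epoch)
  frozen_enc <- "encoder" %in% model$spec$frozen
  opt <- list(head = adam_init(model$head),
              enc = if (!frozen_enc) adam_init(model$enc_params),
              ctx = if (!is.null(model$ctx_params)) adam_init(model$ctx_params))
  step <- 0L
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample(undersample_epoch(labels))
    ep_loss <- 0; ep_n <- 0L
    for (b0 in seq(1L, length(idx), by = cfg$batch_size)) {
      bidx <- idx[b0:min(b0 + cfg$batch_size - 1L, length(idx))]
      g_head <- tree_zeros_like(model$head)
      g_enc <- if (!frozen_enc) tree_zeros_like(model$enc_params)
      g_ctx <- if (!is.null(model$ctx_params)) tree_zeros_like(model$ctx_params)
      for (i in bidx) {
        fwd <- .ft_forward(model, trials[[i]], train = TRUE,
                           reg_cfg = cfg$reg, keep_cache = TRUE)
        z <- fwd$logits
        p <- exp(z - logsumexp(z))
        ep_loss <- ep_loss - log(p[lab_int[i]]); ep_n <- ep_n + 1L
        dz <- p; dz[lab_int[i]] <- dz[lab_int[i]] - 1
        dz <- dz / length(bidx)
        gr <- .ft_backward(model, fwd, dz)
        g_head <- tree_map2(`+`, g_head, gr$head)
        if (!frozen_enc && !is.null(gr$enc)) g_enc <- tree_map2(`+`, g_enc, gr$enc)
        if (!is.null(g_ctx) && !is.null(gr$ctx)) g_ctx <- tree_map2(`+`, g_ctx, gr$ctx)
      }
      lr <- lr_schedule(step, sched)
      step <- step + 1L
      up <- adam_step(model$head, g_head, opt$head, lr, cfg$weight_decay)
      model$head <- up$params; opt$head <- up$state
      if (!frozen_enc) {
        up <- adam_step(model$enc_params, g_enc, opt$enc, lr, cfg$weight_decay)
        model$enc_params <- up$params; opt$enc <- up$state
      }
      if (!is.null(g_ctx)) {
        up <- adam_step(model$ctx_params, g_ctx, opt$ctx, lr, cfg$weight_decay)
        model$ctx_params <- up$params; opt$ctx <- up$state
      }
    }
    hist[ep] <- ep_loss / ep_n
  }
  attr(model, "history") <- hist
  model
}

#' Predict class probabilities for trials
#' @param model A trained `finetune_model`.
#' @param trials List of 20 x T trial matrices.
#' @return Matrix of class probabilities (trials x classes).
#' @export
predict_finetune <- function(model, trials) {
  t(vapply(trials, function(tr) {
    z <- .ft_forward(model, tr, train = FALSE)$logits
    exp(z - logsumexp(z))
  }, numeric(model$n_classes)))
}

#' Classification metrics
#'
#' @param predictions Predicted class labels (BAC/accuracy) — ignored
#'   for AUROC.
#' @param labels True labels.
#' @param kind `"BAC"` (mean per-class recall), `"accuracy"`, or
#'   `"AUROC"` (binary; requires `scores`).
#' @param scores Scores for the positive class (second factor level),
#'   AUROC only.
#' @return Value in `[0, 1]`.
#' @export
metric <- function(predictions, labels, kind = c("BAC", "accuracy", "AUROC"),
                   scores = NULL) {
  kind <- match.arg(kind)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("undefined metric: test fold contains a single class")
  }
  if (kind == "accuracy") {
    return(mean(as.character(predictions) == as.character(labels)))
  }
  if (kind == "BAC") {
    recalls <- vapply(levels(labels), function(cl) {
      mean(as.character(predictions)[labels == cl] == cl)
    }, numeric(1))
    return(mean(recalls))
  }
  stopifnot(!is.null(scores), nlevels(labels) == 2L)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 levels = levels(labels), direction = "<")))
}

#' Normalize a metric from chance (0) to perfect (1)
#' @param value Raw metric value.
#' @param chance_level Chance level (< 1): `1/n_classes` for
#'   accuracy/BAC, 0.5 for AUROC.
#' @return `(value - chance) / (1 - chance)`; may be negative.
#' @export
normalize_metric <- function(value, chance_level) {
  stopifnot(chance_level < 1)
  (value - chance_level) / (1 - chance_level)
}

#' Leave-subjects-out fine-tuning evaluation
#'
#' Partitions subjects into folds (subjects are atomic), trains one
#' model per fold on the remaining subjects, evaluates held-out
#' subjects, and summarizes with a bootstrap confidence interval over
#' subject means.
#'
#' @param trials List of 20 x T trial matrices.
#' @param labels Class labels, one per trial.
#' @param subjects Subject identifier per trial.
#' @param variant Fine-tuning variant 1-6.
#' @param checkpoint Checkpoint list (or NULL for variants 3, 5).
#' @param n_folds Number of subject folds.
#' @param metric_kind `"BAC"`, `"accuracy"`, or `"AUROC"`.
#' @param cfg A `finetune_config`.
#' @param enc_cfg,ctx_cfg Configs for from-scratch variants.
#' @param n_boot Bootstrap resamples for the 0.95 CI.
#' @param seed Seed.
#' @return List: `table` (per-subject metrics), `summary` (mean, CI).
#' @export
run_finetune <- function(trials, labels, subjects, variant, checkpoint = NULL,
                         n_folds = 2L, metric_kind = "BAC",
                         cfg = finetune_config(),
                         enc_cfg = encoder_config(),
                         ctx_cfg = contextualizer_config(),
                         n_boot = 1000L, seed = 1L) {
  labels <- factor(labels)
  subjects <- as.character(subjects)
  subj <- unique(subjects)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(n_folds), length.out = length(subj)))
  names(fold_of) <- subj
  rows <- list()
  for (f in seq_len(n_folds)) {
    test_subj <- subj[fold_of == f]
    tr_idx <- which(!(subjects %in% test_subj))
    model <- build_finetune_model(variant, checkpoint,
                                  n_classes = nlevels(labels),
                                  enc_cfg = enc_cfg, ctx_cfg = ctx_cfg,
                                  seed = seed + f)
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f
    model <- train_finetune(model, trials[tr_idx], labels[tr_idx], cfg_f)
    for (s in test_subj) {
      te_idx <- which(subjects == s)
      if (length(unique(labels[te_idx])) < 2L) {
        message(sprintf("subject %s skipped: single-class test fold", s))
        next
      }
      probs <- predict_finetune(model, trials[te_idx])
      pred <- levels(labels)[max.col(probs, ties.method = "first")]
      val <- metric(pred, labels[te_idx], metric_kind,
                    scores = probs[, min(2L, ncol(probs))])
      rows[[length(rows) + 1L]] <- data.frame(variant = variant, fold = f,
                                              subject = s, metric = metric_kind,
                                              value = val)
    }
  }
  tab <- do.call(rbind, rows)
  vals <- tab$value
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(vals[sample.int(length(vals), replace = TRUE)])
  }, numeric(1))
  chance <- if (metric_kind == "AUROC") 0.5 else 1 / nlevels(labels)
  summary <- data.frame(variant = variant, metric = metric_kind,
                        mean = mean(vals),
                        ci_lo = stats::quantile(boots, 0.025, names = FALSE),
                        ci_hi = stats::quantile(boots, 0.975, names = FALSE),
                        normalized_mean = normalize_metric(mean(vals), chance),
                        n_subjects = nrow(tab))
  list(table = tab, summary = summary)
}
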