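#' Pre-training configuration
#'
#' Span-masking, negative-sampling, loss and optimization settings for
#' the masked contrastive objective.
#'
#' @param p_mask Per-position probability of starting a masked span.
#' @param span Masked span length in BENDR steps.
#' @param n_negatives Distractors per masked position.
#' @param kappa Softmax temperature of the contrastive loss.
#' @param act_penalty_weight Weight of the mean-squared-activation term.
#' @param weight_decay Decoupled Adam weight decay.
#' @param warmup_frac Fraction of steps for the linear warm-up.
#' @param total_steps Total optimization steps.
#' @param peak_lr Peak learning rate.
#' @param batch_size Sequences per step.
#' @param seed RNG seed for all stochastic components.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(p_mask = 0.065, span = 10L, n_negatives = 20L,
                            kappa = 0.1, act_penalty_weight = 1,
                            weight_decay = 0.01, warmup_frac = 0.05,
                            total_steps = 1000L, peak_lr = 1e-4,
                            batch_size = 8L, seed = 1L) {
  stopifnot(p_mask >= 0, p_mask <= 1, span >= 1L, n_negatives >= 1L,
            kappa > 0, warmup_frac > 0, warmup_frac < 1)
  structure(list(p_mask = p_mask, span = as.integer(span),
                 n_negatives = as.integer(n_negatives), kappa = kappa,
                 act_penalty_weight = act_penalty_weight,
                 weight_decay = weight_decay, warmup_frac = warmup_frac,
                 total_steps = as.integer(total_steps), peak_lr = peak_lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "pretrain_config")
}

.make_mask_bool <- function(starts, span, L) {
  mb <- logical(L)
  for (s in starts) mb[s:min(L, s + span - 1L)] <- TRUE
  mb
}

#' Sample a training mask plan
#'
#' Each position independently begins a contiguous masked span of
#' `span` steps with probability `p_mask`; spans may overlap and are
#' truncated at the sequence end. An interior position is therefore
#' masked with probability `1 - (1 - p_mask)^span`.
#'
#' @param L Sequence length in BENDR steps.
#' @param cfg A `pretrain_config`.
#' @return A `mask_plan`: list with `starts` (1-based, sorted), `span`,
#'   `mask_bool`.
#' @export
sample_mask_plan <- function(L, cfg) {
  stopifnot(L >= 1L)
  starts <- which(stats::runif(L) < cfg$p_mask)
  structure(list(starts = starts, span = cfg$span,
                 mask_bool = .make_mask_bool(starts, cfg$span, L)),
            class = "mask_plan")
}

#' Sample contrastive candidates for one masked position
#'
#' Draws `n_negatives` distractor indices uniformly with replacement
#' from the same sequence, excluding the target position; the candidate
#' set is the target plus those distractors.
#'
#' @param L Sequence length.
#' @param t Target position (1-based).
#' @param cfg A `pretrain_config`.
#' @return Integer vector of negative indices (length `n_negatives`).
#' @export
sample_negative_indices <- function(L, t, cfg) {
  if (L < 2L) stop("cannot sample negatives from a length-1 sequence")
  pool <- seq_len(L)[-t]
  pool[sample.int(L - 1L, cfg$n_negatives, replace = TRUE)]
}

#' Cosine similarity
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Contrastive loss at one masked position
#'
#' Negative log-softmax (temperature `kappa`) over the cosine
#' similarities between the contextual output and the candidate set
#' (true target plus distractors), evaluated at the true target.
#'
#' @param c_t Contextual output vector.
#' @param cands Candidate matrix, rows = candidates, row 1 = target.
#' @param kappa Temperature.
#' @param grad Also return analytic gradients.
#' @return Loss (scalar), or if `grad` a list with `loss`, `correct`
#'   (target similarity strictly maximal), `dc` and `dcands`.
#' @export
contrastive_loss <- function(c_t, cands, kappa = 0.1, grad = FALSE) {
  cands <- as.matrix(cands)
  nc <- sqrt(sum(c_t^2))
  nb <- sqrt(rowSums(cands^2))
  if (nc == 0 || any(nb == 0)) {
    stop("cosine similarity undefined for a zero vector")
  }
  dots <- as.numeric(cands %*% c_t)
  cos <- dots / (nc * nb)
  s <- cos / kappa
  lse <- logsumexp(s)
  loss <- unname(lse - s[1L])
  if (!is.finite(loss)) stop("non-finite contrastive loss")
  if (!grad) return(loss)
  p <- exp(s - lse)
  dls <- p; dls[1L] <- dls[1L] - 1          # dL/ds_j
  # dcos_j/dc = b_j/(|c||b_j|) - cos_j * c/|c|^2
  w <- dls / kappa
  dc <- colSums(cands * (w / (nc * nb))) - sum(w * cos) * c_t / nc^2
  dcands <- outer(w / (nc * nb), c_t) - (w * cos / nb^2) * cands
  list(loss = loss, correct = all(cos[1L] > cos[-1L]),
       dc = dc, dcands = dcands)
}

#' Batched contrastive loss over many masked positions
#'
#' Vectorized equivalent of [contrastive_loss()] applied row-wise: for
#' each masked position, row i of `Cm` is scored against the candidate
#' rows `b[I[i, ], ]` (column 1 of `I` is the target index).
#'
#' @param Cm Contextual outputs at the masked positions (n_m x d).
#' @param b Unmasked BENDR matrix (L x d) supplying the candidates.
#' @param I Candidate index matrix (n_m x (1 + n_negatives)).
#' @param kappa Temperature.
#' @return List: `loss_sum`, `n_correct` (strict-argmax hits), `dC`
#'   (n_m x d), `db` (L x d, candidate gradients accumulated by index).
#' @export
contrastive_loss_batch <- function(Cm, b, I, kappa = 0.1) {
  nm <- nrow(Cm); k <- ncol(I); d <- ncol(b)
  nb <- sqrt(rowSums(b * b))
  nc <- sqrt(rowSums(Cm * Cm))
  if (any(nb == 0) || any(nc == 0)) {
    stop("cosine similarity undefined for a zero vector")
  }
  flat <- as.vector(t(I))
  gidx <- rep(seq_len(nm), each = k)
  B <- b[flat, , drop = FALSE]
  Crep <- Cm[gidx, , drop = FALSE]
  nbf <- nb[flat]; ncf <- nc[gidx]
  cosf <- rowSums(B * Crep) / (ncf * nbf)
  S <- matrix(cosf, nm, k, byrow = TRUE) / kappa
  mx <- S[cbind(seq_len(nm), max.col(S, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(S - mx)))
  loss <- lse - S[, 1L]
  if (!all(is.finite(loss))) stop("non-finite contrastive loss")
  Sd <- S[, -1L, drop = FALSE]
  best_d <- Sd[cbind(seq_len(nm), max.col(Sd, ties.method = "first"))]
  n_correct <- sum(S[, 1L] > best_d)
  P <- exp(S - lse)
  W <- P; W[, 1L] <- W[, 1L] - 1
  W <- W / kappa
  wf <- as.vector(t(W))
  t1 <- rowsum(B * (wf / (ncf * nbf)), gidx)
  s2 <- rowSums(W * matrix(cosf, nm, k, byrow = TRUE))
  dC <- t1 - (s2 / nc^2) * Cm
  dB <- Crep * (wf / (ncf * nbf)) - B * (wf * cosf / nbf^2)
  agg <- rowsum(dB, flat)
  db <- matrix(0, nrow(b), d)
  db[as.integer(rownames(agg)), ] <- agg
  list(loss_sum = sum(loss), n_correct = n_correct, dC = dC, db = db)
}

#' Mean squared activation penalty
#' @param b BENDR matrix or `bendr_sequence`.
#' @return Mean of squared entries.
#' @export
activation_penalty <- function(b) {
  if (inherits(b, "bendr_sequence")) b <- b$vectors
  mean(b^2)
}

#' Cosine learning-rate schedule with linear warm-up
#'
#' Linear ramp from 0 to `peak_lr` over `warmup_frac * total_steps`,
#' then a half-cosine decay back to 0.
#'
#' @param step Current step (0-based, up to `total_steps`).
#' @param cfg A list with `peak_lr`, `warmup_frac`, `total_steps`.
#' @return Learning rate.
#' @export
lr_schedule <- function(step, cfg) {
  w <- cfg$warmup_frac * cfg$total_steps
  if (step <= w) return(cfg$peak_lr * step / w)
  cfg$peak_lr * 0.5 * (1 + cos(pi * (step - w) / (cfg$total_steps - w)))
}

#' One pre-training step
#'
#' Encodes each window, samples a span mask, replaces masked positions
#' with the learned mask vector, prepends the start token, runs the
#' contextualizer in train mode, computes the mean contrastive loss
#' over all masked positions of the batch plus the weighted activation
#' penalty, backpropagates through both stages, and applies one Adam
#' update with the scheduled learning rate.
#'
#' @param batch List of `harmonized_sequence` windows (or 20 x T
#'   matrices).
#' @param model List with `enc_params`, `ctx_params`, `enc_cfg`,
#'   `ctx_cfg`.
#' @param opt_state List with `enc` and `ctx` Adam states.
#' @param cfg A `pretrain_config`.
#' @param step Current step index (for the schedule).
#' @return List: `model`, `opt_state`, and `metrics` (contrastive,
#'   penalty, total, accuracy, lr, n_masked).
#' @export
pretrain_step <- function(batch, model, opt_state, cfg, step) {
  enc_p <- model$enc_params; ctx_p <- model$ctx_params
  enc_cfg <- model$enc_cfg; ctx_cfg <- model$ctx_cfg
  denc_tot <- tree_zeros_like(enc_p)
  dctx_tot <- tree_zeros_like(ctx_p)

  seq_data <- list()
  n_masked_tot <- 0L
  n_entries_tot <- 0
  for (sq in batch) {
    x <- if (inherits(sq, "harmonized_sequence")) t(sq$data) else t(as.matrix(sq))
    ef <- encoder_forward(x, enc_p, enc_cfg, keep_cache = TRUE)
    b <- ef$out
    L <- nrow(b)
    plan <- sample_mask_plan(L, cfg)
    if (!any(plan$mask_bool)) plan <- sample_mask_plan(L, cfg)
    if (!any(plan$mask_bool)) next
    seq_data[[length(seq_data) + 1L]] <- list(x = x, ef = ef, b = b, plan = plan)
    n_masked_tot <- n_masked_tot + sum(plan$mask_bool)
    n_entries_tot <- n_entries_tot + length(b)
  }
  if (length(seq_data) == 0L) {
    return(list(model = model, opt_state = opt_state,
                metrics = list(contrastive = NA_real_, penalty = NA_real_,
                               total = NA_real_, accuracy = NA_real_,
                               lr = lr_schedule(step, cfg), n_masked = 0L,
                               skipped = TRUE)))
  }

  loss_contr <- 0; penalty_sum <- 0; n_correct <- 0L
  for (sd in seq_data) {
    b <- sd$b; plan <- sd$plan; L <- nrow(b)
    q <- apply_mask(b, plan, ctx_p$mask_vector)
    q2 <- prepend_start_token(q, ctx_cfg)
    co <- contextualize(q2, ctx_p, ctx_cfg, train = TRUE, keep_cache = TRUE)
    cseq <- co$sequence_out
    ts <- which(plan$mask_bool)
    negmat <- t(vapply(ts, function(t) sample_negative_indices(L, t, cfg),
                       integer(cfg$n_negatives)))
    bl <- contrastive_loss_batch(cseq[ts, , drop = FALSE], b,
                                 cbind(ts, negmat), cfg$kappa)
    loss_contr <- loss_contr + bl$loss_sum
    n_correct <- n_correct + bl$n_correct
    dc_seq <- matrix(0, L, ncol(b))
    dc_seq[ts, ] <- bl$dC / n_masked_tot
    db <- bl$db / n_masked_tot
    # activation penalty over the full unmasked BENDR of the batch
    penalty_sum <- penalty_sum + sum(b^2)
    db <- db + cfg$act_penalty_weight * 2 * b / n_entries_tot
    cb <- contextualize_backward(NULL, dc_seq, co$cache, ctx_p, ctx_cfg)
    dq2 <- cb$dq
    dq <- dq2[-1L, , drop = FALSE]
    dm <- colSums(dq[plan$mask_bool, , drop = FALSE])
    db[!plan$mask_bool, ] <- db[!plan$mask_bool, ] +
      dq[!plan$mask_bool, , drop = FALSE]
    cb$dparams$mask_vector <- dm
    dctx_tot <- tree_map2(`+`, dctx_tot, cb$dparams)
    eb <- encoder_backward(db, sd$ef$cache, enc_p, enc_cfg)
    denc_tot <- tree_map2(`+`, denc_tot, eb$dparams)
  }

  contrastive <- loss_contr / n_masked_tot
  penalty <- cfg$act_penalty_weight * penalty_sum / n_entries_tot
  lr <- lr_schedule(step, cfg)
  up_e <- adam_step(enc_p, denc_tot, opt_state$enc, lr, cfg$weight_decay)
  up_c <- adam_step(ctx_p, dctx_tot, opt_state$ctx, lr, cfg$weight_decay)
  model$enc_params <- up_e$params
  model$ctx_params <- up_c$params
  list(model = model,
       opt_state = list(enc = up_e$state, ctx = up_c$state),
       metrics = list(contrastive = contrastive, penalty = penalty,
                      total = contrastive + penalty,
                      accuracy = n_correct / n_masked_tot,
                      lr = lr, n_masked = n_masked_tot, skipped = FALSE))
}

#' Build an untrained model (encoder + contextualizer)
#' @param enc_cfg,ctx_cfg Stage configurations.
#' @param seed Integer seed; the two stages use derived sub-seeds.
#' @return Model list with parameter trees and configurations.
#' @export
build_model <- function(enc_cfg = encoder_config(),
                        ctx_cfg = contextualizer_config(), seed = 1L) {
  stopifnot(ctx_cfg$bendr_dim == enc_cfg$filters)
  list(enc_params = encoder_init(enc_cfg, seed = seed),
       ctx_params = init_tfixup(ctx_cfg, seed = seed + 1L),
       enc_cfg = enc_cfg, ctx_cfg = ctx_cfg)
}

#' Run the pre-training loop
#'
#' Samples `batch_size` windows per step (uniformly with replacement
#' from the corpus), executes [pretrain_step()], and optionally appends
#' one metrics row per step to a tab-separated log.
#'
#' @param windows List of `harmonized_sequence` training windows.
#' @param model Model from [build_model()] (or a loaded checkpoint).
#' @param cfg A `pretrain_config`.
#' @param metrics_file Optional path for the append-only metrics log.
#' @param opt_state Optional Adam state (to resume).
#' @param start_step First step index (to resume).
#' @param verbose Print progress every 100 steps.
#' @return List: trained `model`, `opt_state`, `history` data.frame.
#' @export
pretrain_run <- function(windows, model, cfg, metrics_file = NULL,
                         opt_state = NULL, start_step = 0L, verbose = FALSE) {
  set.seed(cfg$seed)
  if (is.null(opt_state)) {
    opt_state <- list(enc = adam_init(model$enc_params),
                      ctx = adam_init(model$ctx_params))
  }
  hist <- vector("list", cfg$total_steps - start_step)
  if (!is.null(metrics_file) && !file.exists(metrics_file)) {
    cat("step\tcontrastive\tpenalty\ttotal\taccuracy\tlr\n",
        file = metrics_file)
  }
  hi <- 0L
  for (step in seq.int(start_step, cfg$total_steps - 1L)) {
    idx <- sample.int(length(windows), cfg$batch_size, replace = TRUE)
    res <- pretrain_step(windows[idx], model, opt_state, cfg, step)
    model <- res$model; opt_state <- res$opt_state
    m <- res$metrics
    hi <- hi + 1L
    hist[[hi]] <- data.frame(step = step, contrastive = m$contrastive,
                             penalty = m$penalty, total = m$total,
                             accuracy = m$accuracy, lr = m$lr)
    if (!is.null(metrics_file)) {
      cat(sprintf("%d\t%.6g\t%.6g\t%.6g\t%.4f\t%.3g\n", step,
                  m$contrastive, m$penalty, m$total, m$accuracy, m$lr),
          file = metrics_file, append = TRUE)
    }
    if (verbose && step %% 100L == 0L) {
      message(sprintf("step %d: loss %.4f (contrastive %.4f) acc %.3f",
                      step, m$total, m$contrastive, m$accuracy))
    }
  }
  list(model = model, opt_state = opt_state,
       history = do.call(rbind, hist[seq_len(hi)]))
}
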