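# Shared fixtures. Heavy objects are built once per test run and cached
# in this environment.

.fix <- new.env(parent = emptyenv())

tiny_enc_cfg <- function() encoder_config(filters = 64L, norm_groups = 16L)

tiny_ctx_cfg <- function(...) {
  contextualizer_config(layers = 2L, heads = 4L, d_model = 64L, d_ff = 128L,
                        bendr_dim = 64L, ...)
}

# deterministic multi-rate synthetic corpus, harmonized, plus 20-s
# windows split into train (subjects 1-5) and held-out (subject 6)
fixture_corpus <- function() {
  if (!is.null(.fix$corpus)) return(.fix$corpus)
  sc <- synth_config(n_subjects = 6, duration_s = 120, seed = 42)
  recs <- lapply(1:6, function(s) generate_recording(sc, s))
  harm <- lapply(recs, function(r) {
    if (r$sfreq > 512) r <- apply_antialias(r, 120)
    resample_to_target(r, 256)
  })
  stats <- compute_dataset_stats(harm)
  hs <- lapply(harm, harmonize_recording, map = NULL, stats = stats)
  .fix$corpus <- list(
    config = sc, recordings = recs, harmonized = hs, stats = stats,
    train_windows = unlist(lapply(hs[1:5], window_pretrain, win_s = 20),
                           recursive = FALSE),
    held_windows = window_pretrain(hs[[6]], 20))
  .fix$corpus
}

# a small untrained tiny model (shared read-only)
fixture_tiny_model <- function() {
  if (is.null(.fix$tiny_model)) {
    .fix$tiny_model <- build_model(tiny_enc_cfg(), tiny_ctx_cfg(), seed = 11)
  }
  .fix$tiny_model
}

# band-power of one channel in [f_lo, f_hi] via the periodogram
band_power <- function(x, fs, f_lo, f_hi) {
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = TRUE)
  sum(pg$spec[pg$freq >= f_lo & pg$freq <= f_hi])
}

# oracle classifier for the lateralized band-power effect: predicts "A"
# when alpha power at the first effect channel exceeds the second
oracle_lateralized <- function(recordings, freq = 10,
                               channels = c("C3", "C4")) {
  vapply(recordings, function(r) {
    i1 <- match(channels[1], r$ch_names)
    i2 <- match(channels[2], r$ch_names)
    p1 <- band_power(r$data[i1, ], r$sfreq, freq - 2, freq + 2)
    p2 <- band_power(r$data[i2, ], r$sfreq, freq - 2, freq + 2)
    if (p1 > p2) "A" else "B"
  }, character(1))
}

# labeled separable / null trial sets (cached); a prominent 30 uV
# effect rhythm over 6-s trials is the standard downstream fixture
fixture_trials <- function(ratio, n_per_class = 40L, seed = 5L,
                           trial_s = 6, amplitude = 30) {
  key <- sprintf("trials_%g_%d_%d_%g_%g", ratio, n_per_class, seed,
                 trial_s, amplitude)
  if (is.null(.fix[[key]])) {
    sc <- synth_config(seed = seed)
    .fix[[key]] <- generate_labeled_trials(
      sc, effect = list(kind = "lateralized_bandpower", freq = 10,
                        ratio = ratio, amplitude = amplitude),
      n_per_class = n_per_class, trial_s = trial_s, seed = seed)
  }
  .fix[[key]]
}

# harmonize trials with shared stats -> list of 20 x T matrices
harmonize_trials <- function(tr) {
  stats <- compute_dataset_stats(tr$recordings)
  lapply(tr$recordings, function(r) harmonize_recording(r, stats = stats)$data)
}

# The desk-scale pre-training study: 8 subjects x 240 s at four rates,
# 15-s windows, a 2-layer / d = 64 / 64-filter model trained 2,000
# steps per seed. Seeds run until two reach the target accuracy (or
# all three have run); the first trained model doubles as the
# pre-trained checkpoint for downstream fixtures.
fixture_learning_run <- function(target = 3 / 21) {
  if (!is.null(.fix$learning)) return(.fix$learning)
  sc <- synth_config(n_subjects = 8, duration_s = 240, seed = 42,
                     sfreqs = c(256, 160, 250, 100))
  recs <- lapply(1:8, function(s) generate_recording(sc, s))
  harm <- lapply(recs, resample_to_target, target_hz = 256)
  stats <- compute_dataset_stats(harm)
  hs <- lapply(harm, harmonize_recording, map = NULL, stats = stats)
  wins <- unlist(lapply(hs, window_pretrain, win_s = 15), recursive = FALSE)
  eval_sub <- wins[seq(1, length(wins), by = 4)]
  ec <- tiny_enc_cfg(); cc <- tiny_ctx_cfg()
  accs <- c(); untrained <- c(); first_model <- NULL
  for (seed in 1:3) {
    pc <- pretrain_config(total_steps = 2000L, peak_lr = 1e-3,
                          batch_size = 2L, seed = seed)
    m <- build_model(ec, cc, seed = seed)
    ev0 <- eval_contrastive(m, eval_sub, pc, seed = 99)
    untrained <- c(untrained, weighted.mean(ev0$accuracy, ev0$n_masked))
    res <- pretrain_run(wins, m, pc)
    ev <- eval_contrastive(res$model, eval_sub, pc, seed = 99)
    accs <- c(accs, weighted.mean(ev$accuracy, ev$n_masked))
    if (is.null(first_model)) first_model <- res$model
    if (sum(accs >= target) >= 2L) break
  }
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(first_model, ckpt, step = 2000L)
  .fix$learning <- list(accs = accs, untrained = untrained,
                        checkpoint = load_checkpoint(ckpt),
                        windows = wins, harmonized = hs,
                        n_eval_positions = sum(
                          vapply(eval_sub, function(w) 10, numeric(1))))
  .fix$learning
}

# largest absolute difference over a parameter tree
tree_max_abs_diff <- function(a, b) {
  tree_sum(function(x) 0, a)  # shape check via recursion
  m <- 0
  walk <- function(x, y) {
    if (is.list(x)) mapply(walk, x, y)
    else m <<- max(m, max(abs(x - y)))
  }
  walk(a, b)
  m
}
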