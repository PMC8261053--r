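# Synthetic multi-subject EEG with controllable oscillatory structure:
# band-limited carriers under slow amplitude envelopes (so the token-
# rate sequence has learnable temporal structure) on top of 1/f noise,
# with per-subject amplitude scales, mixed sampling rates and montages.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# frequency-domain 1/f^alpha noise, unit RMS
.pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2L
  amp <- c(0, (1:nf)^(-alpha / 2))
  phase <- stats::runif(nf + 1L, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- c(half, Conj(rev(half[2:(n - nf)])))
  x <- Re(stats::fft(spec[1:n], inverse = TRUE))
  x / stats::sd(x)
}

#' Synthetic EEG configuration
#'
#' @param n_subjects Number of subjects.
#' @param sfreqs Sampling rates (Hz), assigned to subjects cyclically.
#' @param montages Channel sets, cyclic per subject: `"full19"` (all
#'   canonical electrodes), `"superset"` (canonical plus auxiliaries),
#'   `"pair"` (two SSC-style bipolar derivations).
#' @param duration_s Recording length per subject, seconds.
#' @param components List of oscillatory components, each a list with
#'   `freq` (Hz), `bw` (bandwidth, Hz), `amplitude` (uV), `topo`
#'   (named channel gains; unnamed channels get `base_gain`),
#'   `base_gain`.
#' @param noise_exponent 1/f^alpha noise exponent.
#' @param noise_scale Noise RMS in uV.
#' @param amp_range Per-subject amplitude multiplier range.
#' @param envelope_range_s Envelope modulation timescale range (s); the
#'   default 1-5 s puts predictive structure at the BENDR token rate.
#' @param seed Master seed; all draws are deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 4L,
                         sfreqs = c(256, 160, 250, 2048, 100),
                         montages = c("full19", "superset", "pair"),
                         duration_s = 120,
                         components = NULL,
                         noise_exponent = 1, noise_scale = 5,
                         amp_range = c(0.5, 2),
                         envelope_range_s = c(1, 5),
                         seed = 1L) {
  if (is.null(components)) {
    components <- list(
      list(freq = 10, bw = 1, amplitude = 12,
           topo = c(O1 = 1, O2 = 1, Pz = 0.8, P3 = 0.6, P4 = 0.6),
           base_gain = 0.1),
      list(freq = 5, bw = 1, amplitude = 8,
           topo = c(Fz = 1, F3 = 0.7, F4 = 0.7, Cz = 0.5),
           base_gain = 0.1),
      list(freq = 20, bw = 2, amplitude = 5,
           topo = c(C3 = 1, C4 = 1, Cz = 0.8),
           base_gain = 0.05)
    )
  }
  max_f <- max(vapply(components, function(cc) cc$freq + cc$bw / 2, numeric(1)))
  stopifnot(all(sfreqs > 2 * max_f))
  structure(list(n_subjects = as.integer(n_subjects), sfreqs = sfreqs,
                 montages = montages, duration_s = duration_s,
                 components = components, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, amp_range = amp_range,
                 envelope_range_s = envelope_range_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.montage_channels <- function(kind) {
  switch(kind,
         full19 = canonical_channels(),
         superset = c(canonical_channels(), "EOG1", "EOG2", "ECG", "A1", "A2",
                      "POz", "FC1", "FC2"),
         pair = c("FPz-Cz", "Pz-Oz"),
         stop("unknown montage kind: ", kind))
}

.subject_sfreq <- function(cfg, subject) {
  cfg$sfreqs[((subject - 1L) %% length(cfg$sfreqs)) + 1L]
}

.subject_montage <- function(cfg, subject) {
  cfg$montages[((subject - 1L) %% length(cfg$montages)) + 1L]
}

#' Generate one synthetic recording
#'
#' Band-limited oscillations, amplitude-modulated by slow sinusoidal
#' envelopes, plus 1/f noise, scaled by a per-subject amplitude factor.
#' Deterministic given the configuration seed and subject index.
#'
#' @param cfg A `synth_config`.
#' @param subject Subject index (1-based).
#' @param duration_s Override of `cfg$duration_s`.
#' @param long_context Use very slow envelopes (20-60 s timescale) so
#'   that context beyond 20 s is informative.
#' @return A `raw_recording`.
#' @export
generate_recording <- function(cfg, subject, duration_s = cfg$duration_s,
                               long_context = FALSE) {
  .with_seed(cfg$seed * 1000L + subject, {
    fs <- .subject_sfreq(cfg, subject)
    chans <- .montage_channels(.subject_montage(cfg, subject))
    n <- as.integer(round(duration_s * fs))
    tt <- (seq_len(n) - 1) / fs
    subj_scale <- stats::runif(1, cfg$amp_range[1], cfg$amp_range[2])
    data <- matrix(0, length(chans), n)
    canon_of <- vapply(chans, .normalize_ch_name, character(1))
    for (cc in cfg$components) {
      f <- stats::runif(1, cc$freq - cc$bw / 2, cc$freq + cc$bw / 2)
      carrier <- sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      if (long_context) {
        f_env <- stats::runif(1, 1 / 60, 1 / 20)
      } else {
        f_env <- stats::runif(1, 1 / cfg$envelope_range_s[2],
                              1 / cfg$envelope_range_s[1])
      }
      env <- pmax(0, 1 + 0.9 * sin(2 * pi * f_env * tt +
                                     stats::runif(1, 0, 2 * pi)))
      src <- cc$amplitude * env * carrier
      base <- if (is.null(cc$base_gain)) 0.1 else cc$base_gain
      gains <- rep(base, length(chans))
      hit <- match(names(cc$topo), canon_of)
      ok <- !is.na(hit)
      gains[hit[ok]] <- cc$topo[ok]
      # auxiliary (non-EEG) channels carry no oscillatory content
      gains[is.na(canon_of)] <- 0
      data <- data + outer(gains, rep(1, n)) *
        matrix(src, length(chans), n, byrow = TRUE)
    }
    for (i in seq_along(chans)) {
      data[i, ] <- data[i, ] +
        cfg$noise_scale * .pink_noise(n, cfg$noise_exponent)
    }
    data <- data * subj_scale
    raw_recording(data, fs, chans, subject_id = sprintf("S%02d", subject),
                  dataset_id = "synthetic")
  })
}

#' Generate labeled trials embedding a class effect
#'
#' Each trial is a short recording on the full 19-electrode montage at
#' 256 Hz with an oscillatory class effect on a 1/f background. For a
#' lateralized band-power effect of size `ratio`, class "A" carries the
#' oscillation `ratio` times stronger over the first effect channel
#' than the second; class "B" is mirrored. `ratio = 1` is the null
#' dataset: classes are exchangeable.
#'
#' @param cfg A `synth_config` (noise settings reused).
#' @param effect List: `kind` (`"lateralized_bandpower"`), `freq` (Hz),
#'   `channels` (2 electrode names, default C3/C4), `ratio`,
#'   `amplitude` (uV).
#' @param n_per_class Trials per class: scalar, or named vector for
#'   imbalance (e.g. `c(A = 100, B = 25)`).
#' @param trial_s Trial length in seconds.
#' @param seed Seed.
#' @param n_subjects Trials are attributed to this many subjects,
#'   round-robin.
#' @return List: `recordings` (list of `raw_recording`), `labels`,
#'   `subjects`.
#' @export
generate_labeled_trials <- function(cfg, effect, n_per_class, trial_s = 4,
                                    seed = 1L, n_subjects = 4L) {
  stopifnot(effect$kind == "lateralized_bandpower")
  if (is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class[1], 2), c("A", "B"))
  }
  ch_eff <- if (is.null(effect$channels)) c("C3", "C4") else effect$channels
  amp <- if (is.null(effect$amplitude)) 10 else effect$amplitude
  .with_seed(seed, {
    chans <- canonical_channels()
    fs <- 256
    n <- as.integer(round(trial_s * fs))
    tt <- (seq_len(n) - 1) / fs
    labels <- rep(names(n_per_class), n_per_class)
    labels <- sample(labels)
    recs <- vector("list", length(labels))
    i1 <- match(ch_eff[1], chans); i2 <- match(ch_eff[2], chans)
    for (i in seq_along(labels)) {
      data <- matrix(0, length(chans), n)
      for (r in seq_along(chans)) {
        data[r, ] <- cfg$noise_scale * .pink_noise(n, cfg$noise_exponent)
      }
      f <- stats::runif(1, effect$freq - 0.5, effect$freq + 0.5)
      env <- pmax(0, 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.3, 1) * tt +
                                     stats::runif(1, 0, 2 * pi)))
      osc <- amp * env * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      g <- sqrt(effect$ratio)
      if (labels[i] == "A") {
        data[i1, ] <- data[i1, ] + g * osc
        data[i2, ] <- data[i2, ] + osc / g
      } else {
        data[i1, ] <- data[i1, ] + osc / g
        data[i2, ] <- data[i2, ] + g * osc
      }
      recs[[i]] <- raw_recording(data, fs, chans,
                                 subject_id = sprintf("S%02d",
                                   ((i - 1L) %% n_subjects) + 1L),
                                 dataset_id = "synthetic-trials")
    }
    list(recordings = recs, labels = labels,
         subjects = vapply(recs, function(r) r$subject_id, character(1)))
  })
}

#' Generate a corpus on disk with a manifest
#'
#' Writes one file per subject (EDF or delimited text) plus a
#' `manifest.csv` listing file, subject, rate, and channels.
#'
#' @param cfg A `synth_config`.
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"text"`.
#' @param long_context Passed to [generate_recording()].
#' @return The manifest data.frame, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_corpus <- function(cfg, dir, format = c("edf", "text"),
                            long_context = FALSE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(cfg$n_subjects), function(s) {
    rec <- generate_recording(cfg, s, long_context = long_context)
    ext <- if (format == "edf") "edf" else "tsv"
    fn <- sprintf("subject%02d.%s", s, ext)
    path <- file.path(dir, fn)
    if (format == "edf") write_edf(rec, path) else write_recording_text(rec, path)
    data.frame(file = fn, subject = rec$subject_id, sfreq = rec$sfreq,
               n_channels = nrow(rec$data),
               channels = paste(rec$ch_names, collapse = ";"),
               duration_s = recording_duration(rec))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
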