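#' Dataset-wide amplitude statistics
#'
#' Scans all samples of all recordings in a dataset and records the
#' global minimum and maximum. The resulting range is the denominator of
#' the relative-amplitude channel appended to every harmonized sequence.
#'
#' @param recordings A list of `raw_recording` objects.
#' @return A `dataset_stats` list with `global_min` and `global_max`.
#' @export
compute_dataset_stats <- function(recordings) {
  if (inherits(recordings, "raw_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("no recordings supplied")
  lo <- Inf; hi <- -Inf
  for (rec in recordings) {
    stopifnot(inherits(rec, "raw_recording"))
    lo <- min(lo, min(rec$data))
    hi <- max(hi, max(rec$data))
  }
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("degenerate dataset: global max must exceed global min")
  }
  structure(list(global_min = lo, global_max = hi), class = "dataset_stats")
}

#' Scale a sequence into [-1, 1]
#'
#' Applies one linear weight and offset to the whole sequence (all
#' channels jointly) so its maximum maps to 1 and its minimum to -1.
#' Constant input returns all zeros with a degenerate flag.
#'
#' @param x Numeric vector or matrix.
#' @return List: `scaled`, `trial_min`, `trial_max`, `degenerate`.
#' @export
scale_sequence <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    scaled <- x; scaled[] <- 0
    return(list(scaled = scaled, trial_min = lo, trial_max = hi,
                degenerate = TRUE))
  }
  scaled <- 2 * (x - lo) / (hi - lo) - 1
  list(scaled = scaled, trial_min = lo, trial_max = hi, degenerate = FALSE)
}

#' Relative-amplitude channel value
#'
#' Trial peak-to-peak range divided by the dataset peak-to-peak range.
#' Values above 1 (possible when stats were estimated on a subset) are
#' clamped to 1 with a warning.
#'
#' @param trial_min,trial_max Extremes of the trial before scaling.
#' @param stats A `dataset_stats` object.
#' @return A scalar in `[0, 1]`.
#' @export
amplitude_value <- function(trial_min, trial_max, stats) {
  stopifnot(inherits(stats, "dataset_stats"))
  denom <- stats$global_max - stats$global_min
  val <- (trial_max - trial_min) / denom
  if (val > 1) {
    warning("trial range exceeds dataset range; amplitude clamped to 1")
    val <- 1
  }
  val
}

# Enumerate whole-multiple intermediate rates and pick the one nearest
# the target; ties break toward the higher rate.
.nearest_whole_multiple <- function(sfreq, target) {
  if (sfreq == target) return(list(rate = sfreq, factor = 1L, kind = "none"))
  if (sfreq < target) {
    m <- max(1L, round(target / sfreq))
    cand <- unique(pmax(1L, c(m - 1L, m, m + 1L)))
    rates <- sfreq * cand
    best <- cand[order(abs(rates - target), -rates)][1L]
    list(rate = sfreq * best, factor = as.integer(best), kind = "up")
  } else {
    m <- max(1L, round(sfreq / target))
    cand <- unique(pmax(1L, c(m - 1L, m, m + 1L)))
    rates <- sfreq / cand
    best <- cand[order(abs(rates - target), -rates)][1L]
    list(rate = sfreq / best, factor = as.integer(best), kind = "down")
  }
}

#' Resample a recording to the canonical rate
#'
#' First over- or undersamples by the whole multiple whose resulting
#' rate is nearest the target (sample repetition when going up, plain
#' decimation when going down), then maps onto the exact target rate by
#' nearest-neighbor interpolation. Callers are responsible for removing
#' content above the target Nyquist first (see [apply_antialias()]).
#'
#' @param rec A `raw_recording`.
#' @param target_hz Target sampling rate in Hz (default 256).
#' @return A `raw_recording` at `target_hz`.
#' @export
resample_to_target <- function(rec, target_hz = 256) {
  stopifnot(inherits(rec, "raw_recording"), target_hz > 0)
  if (rec$sfreq == target_hz) return(rec)
  step <- .nearest_whole_multiple(rec$sfreq, target_hz)
  if (abs(step$rate - target_hz) > target_hz) {
    warning("sampling rate too far from target for whole-multiple stage")
  }
  x <- rec$data
  if (step$kind == "up" && step$factor > 1L) {
    x <- x[, rep(seq_len(ncol(x)), each = step$factor), drop = FALSE]
  } else if (step$kind == "down" && step$factor > 1L) {
    x <- x[, seq(1L, ncol(x), by = step$factor), drop = FALSE]
  }
  f_in <- step$rate
  if (f_in != target_hz) {
    n_in <- ncol(x)
    n_out <- round(n_in * target_hz / f_in)
    # 0-based output index j reads input round(j * f_in/f_out), half-up
    j <- seq_len(n_out) - 1
    src <- floor(j * f_in / target_hz + 0.5)
    src <- pmin(pmax(src, 0), n_in - 1) + 1L
    x <- x[, src, drop = FALSE]
  }
  raw_recording(x, target_hz, rec$ch_names, rec$annotations,
                rec$subject_id, rec$dataset_id)
}

#' Anti-aliasing low-pass filter
#'
#' Zero-phase FIR low-pass (Hamming-windowed design via
#' [signal::fir1()], applied forward-backward with
#' [signal::filtfilt()]). The transition band is 10% of the cutoff.
#' A cutoff at or above Nyquist is a no-op with a warning.
#'
#' @param rec A `raw_recording`.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @return A filtered `raw_recording`, same length and rate.
#' @export
apply_antialias <- function(rec, cutoff_hz) {
  stopifnot(inherits(rec, "raw_recording"), cutoff_hz > 0)
  nyq <- rec$sfreq / 2
  if (cutoff_hz >= nyq) {
    warning("cutoff at or above Nyquist; anti-alias filter skipped")
    return(rec)
  }
  trans <- 0.1 * cutoff_hz
  ntaps <- ceiling(3.3 * rec$sfreq / trans)
  ntaps <- min(ntaps, max(8L, floor(ncol(rec$data) / 3) - 1L))
  if (ntaps %% 2L == 1L) ntaps <- ntaps + 1L
  b <- as.numeric(signal::fir1(ntaps, cutoff_hz / nyq, type = "low"))
  out <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(b, 1, ch)))
  if (nrow(rec$data) == 1L) out <- matrix(out, nrow = 1L)
  raw_recording(out, rec$sfreq, rec$ch_names, rec$annotations,
                rec$subject_id, rec$dataset_id)
}

#' Harmonize a recording into the canonical 20 x T representation
#'
#' Places matched channels at their canonical 10/20 indices, drops
#' surplus channels, zero-fills missing ones, scales the whole sequence
#' into `[-1, 1]` with a single weight and offset, and stores the
#' relative-amplitude constant in row 20.
#'
#' @param rec A `raw_recording` already resampled to 256 Hz.
#' @param map A `channel_map` from [build_channel_map()]; built from the
#'   recording's own names when omitted.
#' @param stats A `dataset_stats` object.
#' @return A `harmonized_sequence`: list with `data` (20 x T), `sfreq`,
#'   `amplitude`, `present` (logical 19-vector), provenance tags.
#' @export
harmonize_recording <- function(rec, map = NULL, stats) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$sfreq != 256) {
    stop("recording must be resampled to 256 Hz before harmonization")
  }
  if (is.null(map)) map <- build_channel_map(rec$ch_names)
  if (length(map$source_to_canonical) == 0L) {
    stop("unmappable recording: no channels match the canonical 10/20 set")
  }
  T_len <- ncol(rec$data)
  eeg <- rec$data[map$source_index, , drop = FALSE]
  sc <- scale_sequence(eeg)
  amp <- if (sc$degenerate) 0 else
    amplitude_value(sc$trial_min, sc$trial_max, stats)
  out <- matrix(0, nrow = 20L, ncol = T_len)
  rows <- unname(map$source_to_canonical) + 1L
  out[rows, ] <- sc$scaled
  out[20L, ] <- amp
  present <- logical(19L); present[rows] <- TRUE
  structure(
    list(data = out, sfreq = 256, amplitude = amp, present = present,
         subject_id = rec$subject_id, dataset_id = rec$dataset_id),
    class = "harmonized_sequence"
  )
}

#' @export
print.harmonized_sequence <- function(x, ...) {
  cat(sprintf("<harmonized_sequence> 20 x %d @ 256 Hz, amp %.3f, %d/19 channels\n",
              ncol(x$data), x$amplitude, sum(x$present)))
  invisible(x)
}

#' Cut non-overlapping pre-training windows
#'
#' Tiles the sequence with consecutive windows of `win_s` seconds
#' (15,360 samples at the default 60 s); the trailing remainder is
#' dropped. A sequence shorter than one window yields an empty list.
#'
#' @param seq A `harmonized_sequence`.
#' @param win_s Window length in seconds (default 60).
#' @return List of `harmonized_sequence` windows.
#' @export
window_pretrain <- function(seq, win_s = 60) {
  stopifnot(inherits(seq, "harmonized_sequence"), win_s > 0)
  w <- as.integer(round(win_s * seq$sfreq))
  n <- ncol(seq$data) %/% w
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    out <- seq
    out$data <- seq$data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
    out
  })
}

#' Extract labeled trials around event onsets
#'
#' Crops `length_s`-second trials starting `start_s` seconds relative to
#' each event onset (negative values reach pre-stimulus). Seconds are
#' converted to 0-based sample indices with floor. Trials that would
#' extend past either end of the recording are dropped and counted.
#'
#' @param seq A `harmonized_sequence`.
#' @param events Data.frame with columns `onset` (s) and `label`.
#' @param start_s Trial start relative to onset, seconds (may be < 0).
#' @param length_s Trial length in seconds.
#' @return List with `trials` (list of 20 x n matrices), `labels`, and
#'   `n_dropped`.
#' @export
extract_trials <- function(seq, events, start_s, length_s) {
  stopifnot(inherits(seq, "harmonized_sequence"), length_s > 0)
  events <- as.data.frame(events)
  fs <- seq$sfreq
  n_len <- as.integer(round(length_s * fs))
  T_len <- ncol(seq$data)
  trials <- list(); labels <- character(0); dropped <- 0L
  for (i in seq_len(nrow(events))) {
    s0 <- floor((events$onset[i] + start_s) * fs)   # 0-based
    if (s0 < 0 || s0 + n_len > T_len) { dropped <- dropped + 1L; next }
    trials[[length(trials) + 1L]] <- seq$data[, (s0 + 1L):(s0 + n_len), drop = FALSE]
    labels <- c(labels, as.character(events$label[i]))
  }
  if (dropped > 0L) {
    message(sprintf("extract_trials: dropped %d trial(s) outside the recording", dropped))
  }
  list(trials = trials, labels = labels, n_dropped = dropped)
}
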