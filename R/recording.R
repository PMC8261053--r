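#' Raw EEG recording container
#'
#' A minimal in-memory representation of a multichannel EEG recording:
#' a channels x samples matrix together with its sampling rate, channel
#' names, and optional event annotations.
#'
#' @param data Numeric matrix, channels x samples (microvolt scale).
#' @param sfreq Sampling rate in Hz (> 0).
#' @param ch_names Character vector of channel names, one per row of `data`.
#' @param annotations Optional data.frame with columns `onset` (s),
#'   `duration` (s) and `label`.
#' @param subject_id,dataset_id Optional provenance tags.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, sfreq, ch_names, annotations = NULL,
                          subject_id = NA_character_, dataset_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("recording data must be a finite numeric matrix")
  }
  if (length(sfreq) != 1L || !is.finite(sfreq) || sfreq <= 0) {
    stop("sfreq must be a single positive number")
  }
  ch_names <- as.character(ch_names)
  if (length(ch_names) != nrow(data)) {
    stop("length(ch_names) must equal the number of data rows")
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("onset", "duration", "label") %in% names(annotations)))
  }
  structure(
    list(data = data, sfreq = sfreq, ch_names = ch_names,
         annotations = annotations, subject_id = subject_id,
         dataset_id = dataset_id),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `raw_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sfreq

#' Canonical reduced 10/20 electrode set
#'
#' The 19 electrodes of the unambiguously-placed international 10/20
#' system, in the fixed row order used by every harmonized sequence.
#' Row 20 (index 19, 0-based) is reserved for the relative-amplitude
#' channel.
#'
#' @return Character vector of length 19.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

# Older 10/20 names that alias modern temporal/posterior labels, plus a
# pragmatic frontopolar-midline alias (Fpz is absent from the reduced
# set; sleep montages referenced to it land on Fp1).
.channel_synonyms <- c(t3 = "T7", t4 = "T8", t5 = "P7", t6 = "P8",
                       fpz = "Fp1")

.normalize_ch_name <- function(name) {
  nm <- trimws(name)
  # bipolar derivations (e.g. "FPz-Cz") map to their first electrode
  nm <- sub("-.*$", "", nm)
  # common prefixes in clinical EDF headers ("EEG FP1-REF")
  nm <- sub("^(?i)eeg[ _]*", "", nm, perl = TRUE)
  low <- tolower(nm)
  if (low %in% names(.channel_synonyms)) {
    return(unname(.channel_synonyms[low]))
  }
  canon <- canonical_channels()
  hit <- match(low, tolower(canon))
  if (!is.na(hit)) canon[hit] else NA_character_
}

#' Map recording channels onto the canonical 10/20 layout
#'
#' Matching is case-insensitive, understands the T3/T4/T5/T6 aliases of
#' T7/T8/P7/P8, and maps bipolar derivations (FPz-Cz) to their first
#' electrode. Unmatched channels are recorded as ignored.
#'
#' @param ch_names Character vector of channel names from a recording.
#' @return A `channel_map`: list with `canonical_order` (20 names, the
#'   19 electrodes plus `"AMP"`), `source_to_canonical` (named integer
#'   vector, source index -> canonical 0-based index), and `unmatched`.
#' @export
build_channel_map <- function(ch_names) {
  canon <- canonical_channels()
  mapped <- vapply(ch_names, .normalize_ch_name, character(1))
  idx <- match(mapped, canon) - 1L   # 0-based canonical indices
  hit <- !is.na(idx)
  # injective: first occurrence wins if a name is duplicated
  dup <- hit & duplicated(idx)
  hit[dup] <- FALSE
  src <- which(hit)
  m <- idx[hit]
  names(m) <- ch_names[hit]
  structure(
    list(canonical_order = c(canon, "AMP"),
         source_to_canonical = m,
         source_index = src,
         unmatched = ch_names[!hit]),
    class = "channel_map"
  )
}
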