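# Minimal European Data Format (EDF/EDF+) support: enough to round-trip
# the synthetic corpora and to ingest plain 16-bit EDF recordings with
# 10/20-style channel labels. One data record per second, so sampling
# rates must be whole numbers.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Plain EDF, 16-bit samples, one data record per second. The physical
#' range is taken per channel from the data (symmetric, with a small
#' floor so constant channels stay representable). Annotations, if any,
#' are written to a sidecar CSV next to the file (`<path>.events.csv`).
#'
#' @param rec A `raw_recording` with integer `sfreq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sfreq
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec == 0L) stop("recording shorter than one 1-s data record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmaxv <- pmax(apply(abs(x), 1L, max), 1e-6)
  # use the header-text representation so reader and writer agree
  # exactly; 7 chars leaves room for the minus sign in an 8-char field
  fmt7 <- function(v) {
    for (d in 6:1) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (nchar(s) <= 7L) return(s)
    }
    trimws(formatC(v, digits = 1, format = "g"))
  }
  pmax_txt <- vapply(pmaxv, fmt7, character(1))
  pmaxv <- as.numeric(pmax_txt)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  wr <- function(s, w) writeBin(charToRaw(.pad(s, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(hdr_bytes, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (nm in rec$ch_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)                     # transducer
  for (i in seq_len(ns)) wr("uV", 8)                    # physical dim
  for (i in seq_len(ns)) wr(paste0("-", pmax_txt[i]), 8)
  for (i in seq_len(ns)) wr(pmax_txt[i], 8)
  for (i in seq_len(ns)) wr(-32768L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)                     # prefilter
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  # inverse of the reader's affine map: phys = pmin + g * (dig - dmin)
  gain <- (2 * pmaxv) / 65535
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((x[i, cols] + pmaxv[i]) / gain[i])) - 32768L
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0L) {
    utils::write.csv(rec$annotations, paste0(path, ".events.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

# Parse EDF+ time-stamped annotation lists (TALs). TALs are separated
# by 0x00 bytes; within a TAL, "onset[\x15 duration]" is followed by
# \x14-delimited annotation texts.
.parse_tal <- function(bytes) {
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    label = character(0))
  zero <- bytes == as.raw(0)
  tal_id <- cumsum(zero)
  for (chunk in split(bytes[!zero], tal_id[!zero])) {
    txt <- rawToChar(chunk)
    parts <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    if (length(parts) == 0L) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    if (is.na(onset)) next
    dur <- if (length(head) > 1L) suppressWarnings(as.numeric(head[2])) else 0
    labs <- parts[-1][nzchar(parts[-1])]
    for (lb in labs) {
      out <- rbind(out, data.frame(onset = onset,
                                   duration = ifelse(is.na(dur), 0, dur),
                                   label = lb))
    }
  }
  out
}

#' Read an EDF/EDF+ file
#'
#' Reads 16-bit EDF. An "EDF Annotations" signal, if present, is parsed
#' into onset/duration/label annotations; a sidecar `<path>.events.csv`
#' (as written by [write_edf()]) is also honored. All ordinary signals
#' must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @return A `raw_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_annot <- labels == "EDF Annotations"
  sig <- which(!is_annot)
  if (length(sig) == 0L) stop("EDF file contains no signal channels")
  if (length(unique(spr[sig])) != 1L) {
    stop("mixed per-signal sampling rates are not supported")
  }
  fs <- spr[sig[1]] / rec_dur
  data <- matrix(0, nrow = length(sig), ncol = n_rec * spr[sig[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", spr[i] * 2L))
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2L, endian = "little")
        k <- match(i, sig)
        g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
        cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
        data[k, cols] <- pmin_[i] + g * (dig - dmin_[i])
      }
    }
  }
  ann <- NULL
  if (any(is_annot)) {
    parsed <- .parse_tal(ann_raw)
    if (nrow(parsed) > 0L) ann <- parsed
  }
  side <- paste0(path, ".events.csv")
  if (is.null(ann) && file.exists(side)) {
    ann <- utils::read.csv(side, stringsAsFactors = FALSE)
  }
  raw_recording(data, fs, labels[sig], ann)
}

#' Write a recording as delimited text
#'
#' Fallback plain-text format: a `# sfreq=<Hz>` comment line, a header
#' row of channel names, then one row per sample (tab-separated).
#'
#' @param rec A `raw_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sfreq=%g", rec$sfreq), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = rec$ch_names, quote = FALSE)
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0L) {
    utils::write.csv(rec$annotations, paste0(path, ".events.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a delimited-text recording
#' @param path Path written by [write_recording_text()].
#' @return A `raw_recording`.
#' @export
read_recording_text <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("sfreq=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L) stop("missing '# sfreq=' header line")
  fs <- as.numeric(m[2])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          check.names = FALSE)
  ann <- NULL
  side <- paste0(path, ".events.csv")
  if (file.exists(side)) ann <- utils::read.csv(side, stringsAsFactors = FALSE)
  raw_recording(t(as.matrix(df)), fs, colnames(df), ann)
}

#' Read a recording, dispatching on file extension
#' @param path `.edf` or text file path.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else read_recording_text(path)
}
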