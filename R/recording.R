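#' Multichannel EEG recording container
#'
#' An `eeg_recording` bundles a channel-by-time sample matrix (microvolts)
#' with its sampling rate, channel labels and subject/trial metadata. All
#' pipeline stages take and return this container until features are
#' extracted, at which point results become tibbles.
#'
#' @param samples numeric matrix, channels in rows, samples in columns (µV).
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of channel labels, one per row of
#'   `samples`; labels must be unique after whitespace stripping
#'   (comparison elsewhere is case-insensitive).
#' @param subject_id,trial_id opaque identifiers carried into feature tables.
#' @param task task label (e.g. `"MB2"`, `"MB3"`).
#'
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, rate, channels,
                          subject_id = NA_character_,
                          trial_id = NA_character_,
                          task = NA_character_) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  channels <- trimws(as.character(channels))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (nrow(samples) != length(channels)) {
    abort(sprintf(
      "Number of channel labels (%d) does not match number of sample rows (%d).",
      length(channels), nrow(samples)
    ))
  }
  dup <- unique(channels[duplicated(toupper(channels))])
  if (length(dup)) {
    abort(paste0("Duplicate channel labels: ", paste(dup, collapse = ", ")))
  }
  rownames(samples) <- channels
  structure(
    list(
      samples = samples, rate = as.numeric(rate), channels = channels,
      subject_id = as.character(subject_id), trial_id = as.character(trial_id),
      task = as.character(task)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$rate, ncol(x$samples) / x$rate
  ))
  cat(sprintf(
    "  subject: %s  trial: %s  task: %s\n", x$subject_id, x$trial_id, x$task
  ))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec an `eeg_recording`.
#' @return `n_samples()` the sample count; `duration()` seconds.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$samples) / rec$rate

match_channels <- function(have, want) {
  match(toupper(trimws(want)), toupper(trimws(have)))
}

#' Read an EEG recording from disk
#'
#' Supports European Data Format (EDF, 16-bit integer records) and plain
#' delimited text with a header row of channel labels and one row per
#' sample. Labels are whitespace-stripped; matching throughout the package
#' is case-insensitive.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param rate sampling rate in Hz for delimited input (EDF stores its own).
#' @param sep field separator for delimited input; `NULL` guesses comma/tab.
#' @inheritParams new_recording
#' @return An [new_recording()] object.
#' @export
load_recording <- function(path, format = c("auto", "edf", "delimited"),
                           rate = 500, sep = NULL,
                           subject_id = NA_character_,
                           trial_id = NA_character_, task = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") {
    ed <- read_edf(path)
    new_recording(ed$samples, ed$rate, ed$channels,
      subject_id = subject_id, trial_id = trial_id, task = task
    )
  } else {
    if (is.null(sep)) {
      first <- readLines(path, n = 1L)
      sep <- if (grepl("\t", first)) "\t" else ","
    }
    dat <- read.csv(path, sep = sep, check.names = FALSE)
    labs <- trimws(colnames(dat))
    if (!length(labs) || any(labs == "") || any(grepl("^V?[0-9.]+$", labs))) {
      abort("Delimited input must carry channel labels in its header row.")
    }
    new_recording(t(as.matrix(dat)), rate, labs,
      subject_id = subject_id, trial_id = trial_id, task = task
    )
  }
}

# Minimal EDF reader: 256-byte fixed header, 256 bytes per signal, data as
# little-endian int16 records. Written here because no installed package
# reads EDF; only uniform-rate, equally long signals are supported.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    v <- readChar(con, n, useBytes = TRUE)
    trimws(v)
  }
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) abort("Unreadable EDF header (signal count).")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8) # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    abort("Non-uniform sampling across EDF signals is not supported.")
  }
  if (any(!is.finite(pmin)) || any(!is.finite(pmax)) ||
    any(!is.finite(dmin)) || any(!is.finite(dmax))) {
    abort("Unreadable EDF header (calibration fields).")
  }
  if (any(labels == "")) abort("EDF file has empty channel labels.")
  seek(con, header_bytes)
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L,
                     signed = TRUE, endian = "little")
      out[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[s]) * scale[s] + pmin[s]
    }
  }
  list(samples = out, rate = spr[1] / rec_dur, channels = labels)
}

#' Write a recording as EDF
#'
#' Companion writer to the EDF reader so pipelines (and tests) can
#' round-trip files. Samples are scaled to the int16 range per channel.
#'
#' @inheritParams n_samples
#' @param path output file path.
#' @param record_s data-record duration in seconds; the sample count must be
#'   divisible by `rate * record_s`.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, record_s = 1) {
  spr <- rec$rate * record_s
  if (spr != round(spr)) abort("`rate * record_s` must be an integer.")
  spr <- as.integer(spr)
  if (n_samples(rec) %% spr != 0) {
    abort("Sample count must be a whole number of data records.")
  }
  n_rec <- n_samples(rec) %/% spr
  ns <- length(rec$channels)
  pmax <- apply(abs(rec$samples), 1, max)
  pmax <- ifelse(pmax > 0, pmax, 1)
  pmin <- -pmax
  dmax <- 32767; dmin <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    x <- substr(as.character(x), 1, n)
    writeChar(formatC(x, width = -n), con, eos = NULL)
  }
  pad("0", 8)
  pad("X", 80); pad("Startdate X X X X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256L * (1L + ns), 8)
  pad("", 44)
  pad(n_rec, 8); pad(format(record_s), 8); pad(ns, 4)
  for (l in rec$channels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (p in pmin) pad(formatC(p, digits = 6, format = "g"), 8)
  for (p in pmax) pad(formatC(p, digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) pad(dmin, 8)
  for (i in seq_len(ns)) pad(dmax, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  pminh <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmaxh <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  scale <- (dmax - dmin) / (pmaxh - pminh)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((rec$samples[s, idx] - pminh[s]) * scale[s] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Restrict a recording to the reduced 32-channel montage
#'
#' Keeps only the configured 10-20-based subset (32 labels by default,
#' shipped as `montage32.txt`), preserving the recording's original channel
#' order. Errors if any subset label is absent.
#'
#' @inheritParams n_samples
#' @param montage character vector of labels, or `NULL` for the shipped set.
#' @return An `eeg_recording` with exactly the subset channels.
#' @export
reduced_montage <- function(rec, montage = NULL) {
  if (is.null(montage)) montage <- default_montage32()
  idx <- match_channels(rec$channels, montage)
  if (anyNA(idx)) {
    abort(paste0(
      "Recording is missing reduced-montage channels: ",
      paste(montage[is.na(idx)], collapse = ", ")
    ))
  }
  keep <- sort(idx)
  new_recording(rec$samples[keep, , drop = FALSE], rec$rate,
    rec$channels[keep],
    subject_id = rec$subject_id, trial_id = rec$trial_id, task = rec$task
  )
}

#' The shipped reduced 32-channel montage
#'
#' Standard 10-20 labels present in the 116-channel study montage, padded
#' with common 10-10 positions to 32. A documented stand-in, editable by
#' passing any label file to `read_montage()`.
#'
#' @return Character vector of 32 labels.
#' @export
default_montage32 <- function() {
  read_montage(system.file("extdata", "montage32.txt", package = "neuroload"))
}

#' @rdname default_montage32
#' @param path text file with one channel label per line (`#` comments allowed).
#' @export
read_montage <- function(path) {
  x <- trimws(readLines(path))
  x[!grepl("^#", x) & nzchar(x)]
}
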