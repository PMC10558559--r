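# Welch-averaged one-sided periodogram of one channel. Returns power in
# units^2/Hz on the fs/L grid. Hand-vectorized over segments via mvfft.
welch_psd <- function(x, rate, len, hop, taper) {
  starts <- seq(1L, length(x) - len + 1L, by = hop)
  segs <- vapply(starts, function(s) x[s:(s + len - 1L)] * taper,
    numeric(len)
  )
  X <- mvfft(segs)
  nfreq <- len %/% 2 + 1L
  p <- rowMeans(Mod(X[seq_len(nfreq), , drop = FALSE])^2) /
    (rate * sum(taper^2))
  # one-sided: double all bins except DC (and Nyquist when len is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (len %% 2 == 0) dbl[nfreq] <- 1
  p * dbl
}

#' Power spectral density by short-window FFT
#'
#' Welch-averaged short FFT over Kaiser-tapered windows (1 s at 50%
#' overlap by default), yielding a frequency resolution of 1 Hz at a
#' 500 Hz sampling rate. Power is in µV²/Hz per channel.
#'
#' @inheritParams n_samples
#' @param window_s moving-window length in seconds.
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param kaiser_beta Kaiser taper shape parameter; larger suppresses
#'   sidelobes harder (14 by default).
#' @param mask optional logical vector of rejected 1-s screening segments
#'   (from [artifact_screen()]); windows overlapping a rejected segment are
#'   skipped.
#' @return A `psd_estimate`: list with `freqs` (Hz), `power`
#'   (channels x frequencies), `channels`, `rate`.
#' @export
compute_psd <- function(rec, window_s = 1, overlap = 0.5, kaiser_beta = 14,
                        mask = NULL) {
  len <- round(window_s * rec$rate)
  if (n_samples(rec) < len) {
    abort(sprintf(
      "Recording (%d samples) is shorter than one %g-s window (%d samples).",
      n_samples(rec), window_s, len
    ))
  }
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  hop <- max(1L, round(len * (1 - overlap)))
  taper <- as.numeric(signal::kaiser(len, kaiser_beta))
  x_all <- rec$samples
  if (!is.null(mask) && any(mask)) {
    keep_samples <- rep(TRUE, n_samples(rec))
    seg_len <- round(rec$rate) # screening segments are 1 s
    for (s in which(mask)) {
      keep_samples[((s - 1) * seg_len + 1):min(s * seg_len, n_samples(rec))] <- FALSE
    }
    x_all <- x_all[, keep_samples, drop = FALSE]
    if (ncol(x_all) < len) {
      abort("All data rejected by the artifact mask; no window to estimate from.")
    }
  }
  power <- t(apply(x_all, 1, welch_psd,
    rate = rec$rate, len = len, hop = hop, taper = taper
  ))
  structure(
    list(
      freqs = (seq_len(len %/% 2 + 1L) - 1) * rec$rate / len,
      power = power, channels = rec$channels, rate = rec$rate,
      subject_id = rec$subject_id, trial_id = rec$trial_id, task = rec$task
    ),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d channels, %d frequencies (0-%g Hz)\n",
    nrow(x$power), length(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

# Mean in-band power per channel for one band (inclusive edges).
band_mean_power <- function(psd, lo, hi) {
  sel <- psd$freqs >= lo & psd$freqs <= hi
  if (!any(sel)) abort(sprintf("No frequency bins inside %g-%g Hz.", lo, hi))
  rowMeans(psd$power[, sel, drop = FALSE])
}

#' Region-averaged spectral band-power features
#'
#' Averages PSD within each canonical band per channel, then averages
#' channels within each Brodmann area (or cortex). With the full
#' 116-channel fixture map this yields 84 features at BA level (21 areas x
#' 4 bands) and 16 at cortex level. Ordering is deterministic:
#' region-major, band-minor.
#'
#' @param psd a [compute_psd()] estimate.
#' @param bands band table from [eeg_bands()] (subsettable).
#' @param map a [load_ba_map()] object; `NULL` loads the fixture.
#' @param level aggregate over `"ba"` or `"cortex"`.
#' @return Tibble with columns `subject_id`, `trial_id`, `task`, `metric`,
#'   `region`, `band`, `feature` (`"psd|BA45|beta"`) and `value`.
#' @export
band_power_features <- function(psd, bands = eeg_bands(), map = NULL,
                                level = c("ba", "cortex")) {
  level <- match.arg(level)
  rec_stub <- list(channels = psd$channels)
  assignment <- assign_brodmann(structure(rec_stub, class = "eeg_recording"), map)
  members <- region_members(assignment, level)
  rows <- purrr::pmap(bands, function(band, lo, hi) {
    chan_val <- band_mean_power(psd, lo, hi)
    tibble(
      metric = "psd",
      region = names(members),
      band = band,
      value = vapply(members, function(ix) mean(chan_val[ix]), 0)
    )
  })
  out <- bind_rows(rows) %>%
    mutate(
      region = factor(.data$region, levels = names(members)),
      band = factor(.data$band, levels = bands$band)
    ) %>%
    arrange(.data$region, .data$band) %>%
    mutate(
      region = as.character(.data$region), band = as.character(.data$band),
      feature = paste(.data$metric, .data$region, .data$band, sep = "|"),
      subject_id = psd$subject_id, trial_id = psd$trial_id, task = psd$task
    ) %>%
    select(
      "subject_id", "trial_id", "task", "metric", "region", "band",
      "feature", "value"
    )
  out
}
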