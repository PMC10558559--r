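# Magnitude-squared coherence for all channel pairs, averaged over the
# in-band frequency bins of each requested band. Welch cross-spectra over
# Hann-tapered sub-segments. Returns a named list of N x N matrices.
msc_bands <- function(samples, rate, bands, sub_len, sub_overlap = 0.5) {
  n_chan <- nrow(samples)
  n_time <- ncol(samples)
  hop <- max(1L, round(sub_len * (1 - sub_overlap)))
  starts <- seq(1L, n_time - sub_len + 1L, by = hop)
  if (length(starts) < 3L) {
    abort(sprintf(
      "Segment of %d samples gives only %d sub-segments of %d; at least 3 are required for a non-degenerate coherence estimate.",
      n_time, length(starts), sub_len
    ))
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, sub_len - 1) / (sub_len - 1))
  freqs <- (seq_len(sub_len %/% 2 + 1L) - 1) * rate / sub_len
  bins <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$lo[b] & freqs <= bands$hi[b])
  })
  names(bins) <- bands$band
  use_bins <- sort(unique(unlist(bins)))
  if (!length(use_bins)) abort("No frequency bins fall inside the requested bands.")
  nb <- length(use_bins)
  Sxy <- array(0 + 0i, dim = c(n_chan, n_chan, nb))
  Pxx <- matrix(0, n_chan, nb)
  for (s in starts) {
    seg <- samples[, s:(s + sub_len - 1L), drop = FALSE]
    X <- mvfft(t(seg * rep(taper, each = n_chan)))[use_bins, , drop = FALSE]
    for (k in seq_len(nb)) {
      xf <- X[k, ]
      Sxy[, , k] <- Sxy[, , k] + tcrossprod(Conj(xf), xf)
      Pxx[, k] <- Pxx[, k] + Mod(xf)^2
    }
  }
  out <- lapply(seq_along(bins), function(b) {
    kset <- match(bins[[b]], use_bins)
    acc <- matrix(0, n_chan, n_chan)
    for (k in kset) {
      denom <- tcrossprod(Pxx[, k], Pxx[, k])
      denom[denom <= 0] <- .Machine$double.eps
      acc <- acc + Mod(Sxy[, , k])^2 / denom
    }
    g <- acc / length(kset)
    g <- (g + t(g)) / 2
    g[g > 1] <- 1
    diag(g) <- 1
    dimnames(g) <- list(rownames(samples), rownames(samples))
    g
  })
  names(out) <- bands$band
  out
}

#' Band-averaged coherence adjacency matrix
#'
#' Magnitude-squared coherence between every channel pair, estimated by
#' Welch-averaged cross-spectra over Hann-tapered sub-segments (250
#' samples at 50% overlap by default, i.e. three sub-segments inside a 1-s
#' window at 500 Hz) and averaged over the in-band frequency bins. The
#' result is the symmetric weighted functional-network adjacency matrix
#' with entries in `[0, 1]` and a unit diagonal (self-coherence is
#' uninformative and excluded from downstream metrics).
#'
#' @inheritParams n_samples
#' @param band a band name (`"alpha"`, ...) or one row of [eeg_bands()].
#' @param sub_len sub-segment length in samples (`NULL`: half the sampling
#'   rate, i.e. 0.5 s).
#' @param sub_overlap sub-segment overlap fraction.
#' @return N x N numeric matrix.
#' @export
coherence_matrix <- function(rec, band, sub_len = NULL, sub_overlap = 0.5) {
  if (is.character(band)) band <- eeg_bands(band)
  if (is.null(sub_len)) sub_len <- round(rec$rate / 2)
  msc_bands(rec$samples, rec$rate, band, sub_len, sub_overlap)[[1]]
}

#' Per-window coherence network stack
#'
#' Splits a recording into consecutive windows (1 s by default), drops any
#' rejected by the artifact mask, and computes one coherence adjacency
#' matrix per retained window, in temporal order.
#'
#' @inheritParams coherence_matrix
#' @param window_s window length in seconds.
#' @param mask logical vector of rejected windows ([artifact_screen()]
#'   mask); `NULL` keeps all.
#' @return A `coherence_stack`: list with `band`, `window_s`, `windows`
#'   (list of matrices), `window_index` (original window numbers),
#'   `channels`.
#' @export
windowed_networks <- function(rec, band, window_s = 1, mask = NULL,
                              sub_len = NULL, sub_overlap = 0.5) {
  if (is.character(band)) band <- eeg_bands(band)
  if (is.null(sub_len)) sub_len <- round(rec$rate / 2)
  len <- round(window_s * rec$rate)
  n_win <- n_samples(rec) %/% len
  keep <- seq_len(n_win)
  if (!is.null(mask)) {
    if (length(mask) < n_win) {
      abort("Artifact mask is shorter than the number of windows.")
    }
    keep <- keep[!mask[keep]]
  }
  if (length(keep) < 2L) {
    abort("Fewer than 2 retained windows; temporal features are undefined.")
  }
  wins <- lapply(keep, function(w) {
    idx <- ((w - 1) * len + 1):(w * len)
    msc_bands(rec$samples[, idx, drop = FALSE], rec$rate, band,
      sub_len, sub_overlap
    )[[1]]
  })
  structure(
    list(
      band = band$band, window_s = window_s, windows = wins,
      window_index = keep, channels = rec$channels,
      subject_id = rec$subject_id, trial_id = rec$trial_id, task = rec$task
    ),
    class = "coherence_stack"
  )
}

#' @export
print.coherence_stack <- function(x, ...) {
  cat(sprintf(
    "<coherence_stack> band %s: %d windows of %g s, %d channels\n",
    x$band, length(x$windows), x$window_s, length(x$channels)
  ))
  invisible(x)
}
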