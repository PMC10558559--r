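#' Channel-to-Brodmann-area map
#'
#' Loads the mapping from EEG channel labels to Brodmann areas (BAs) and
#' from BAs to the four cortices (frontal, parietal, occipital, temporal).
#' The shipped fixture covers the 116-channel study montage over 21 BAs;
#' its BA-to-cortex grouping follows standard lobe anatomy and is a
#' documented, editable stand-in.
#'
#' @param path YAML file with `channel_ba` (label -> integer BA) and
#'   `ba_cortex` (BA -> cortex) blocks; `NULL` loads the shipped fixture.
#' @return A `ba_map` object: list with `channel_ba` (named integer vector)
#'   and `ba_cortex` (named character vector).
#' @export
load_ba_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "brodmann_map.yaml", package = "neuroload")
  }
  raw <- yaml::read_yaml(path)
  channel_ba <- vapply(raw$channel_ba, as.integer, 1L)
  ba_cortex <- vapply(raw$ba_cortex, as.character, "")
  if (anyNA(channel_ba)) abort("Non-integer BA in channel_ba block.")
  bas <- sort(unique(channel_ba))
  missing_cx <- setdiff(bas, as.integer(names(ba_cortex)))
  if (length(missing_cx)) {
    abort(paste0(
      "BA(s) without a cortex assignment: ", paste(missing_cx, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(ba_cortex), c("frontal", "parietal", "occipital", "temporal"))
  if (length(bad)) {
    abort(paste0("Unknown cortex label(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(channel_ba = channel_ba, ba_cortex = ba_cortex),
    class = "ba_map"
  )
}

#' @export
print.ba_map <- function(x, ...) {
  cat(sprintf(
    "<ba_map> %d channels over %d Brodmann areas, %d cortices\n",
    length(x$channel_ba), length(unique(x$channel_ba)),
    length(unique(x$ba_cortex))
  ))
  invisible(x)
}

#' Assign recording channels to Brodmann areas
#'
#' Looks every channel of a recording up in a [load_ba_map()] mapping and
#' returns the assignment as a tibble. Unmapped channels are an error
#' unless `drop_unmapped = TRUE`, in which case they are dropped with a
#' warning naming them.
#'
#' @inheritParams n_samples
#' @param map a `ba_map`; `NULL` loads the shipped fixture.
#' @param drop_unmapped drop channels absent from the map instead of erroring.
#' @return Tibble with columns `channel`, `index` (row in the recording),
#'   `ba`, `cortex`.
#' @export
assign_brodmann <- function(rec, map = NULL, drop_unmapped = FALSE) {
  if (is.null(map)) map <- load_ba_map()
  pos <- match_channels(names(map$channel_ba), rec$channels)
  if (anyNA(pos)) {
    miss <- rec$channels[is.na(pos)]
    if (!drop_unmapped) {
      abort(paste0(
        "Channel(s) not present in the BA map: ", paste(miss, collapse = ", "),
        ". Use drop_unmapped = TRUE to discard them."
      ))
    }
    warn(paste0("Dropping unmapped channel(s): ", paste(miss, collapse = ", ")))
  }
  keep <- which(!is.na(pos))
  ba <- unname(map$channel_ba[pos[keep]])
  tibble(
    channel = rec$channels[keep],
    index = keep,
    ba = ba,
    cortex = unname(map$ba_cortex[as.character(ba)])
  )
}

#' Group channel indices by region
#'
#' Turns an [assign_brodmann()] assignment into a named list of
#' channel-index vectors, one per region, in a deterministic order (BAs
#' ascending, or cortices in the fixed
#' frontal/parietal/occipital/temporal order). This is the `regions`
#' input of [integration_recruitment()].
#'
#' @param assignment tibble from [assign_brodmann()].
#' @param level `"ba"` or `"cortex"`.
#' @return Named list of integer vectors.
#' @export
region_members <- function(assignment, level = c("ba", "cortex")) {
  level <- match.arg(level)
  if (level == "ba") {
    key <- paste0("BA", assignment$ba)
    ord <- paste0("BA", sort(unique(assignment$ba)))
  } else {
    key <- assignment$cortex
    ord <- intersect(
      c("frontal", "parietal", "occipital", "temporal"),
      unique(assignment$cortex)
    )
  }
  out <- split(assignment$index, key)[ord]
  if (any(!lengths(out))) abort("Empty region in the channel assignment.")
  out
}

#' The four canonical EEG frequency bands
#'
#' theta 4-8, alpha 8-12, beta 13-35 and gamma 35-65 Hz. The 12-13 Hz gap
#' between alpha and beta is left unassigned on purpose.
#'
#' @param names optional subset of band names, in the returned order.
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function(names = NULL) {
  b <- tibble(
    band = c("theta", "alpha", "beta", "gamma"),
    lo = c(4, 8, 13, 35),
    hi = c(8, 12, 35, 65)
  )
  if (!is.null(names)) {
    bad <- setdiff(names, b$band)
    if (length(bad)) abort(paste0("Unknown band(s): ", paste(bad, collapse = ", ")))
    b <- b[match(names, b$band), ]
  }
  b
}
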