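partition_A <- function(A) {
  if (inherits(A, "partition_matrix")) A <- A$A
  A <- as.matrix(A)
  if (any(A != round(A)) || any(A < 1)) {
    abort("Partition labels must be positive integers.")
  }
  A
}

#' Temporal network flexibility
#'
#' Fraction of consecutive window pairs in which a channel changes its
#' community assignment: `f_i = 1 - (1/(T-1)) * sum_t delta(A[i,t],
#' A[i,t+1])`. 0 means a stable assignment throughout, 1 means the label
#' changes at every transition.
#'
#' @param A a [build_partition_matrix()] object or an integer channel x
#'   window matrix (labels aligned across windows).
#' @return Named numeric vector of per-channel flexibility in `[0, 1]`.
#' @export
temporal_flexibility <- function(A) {
  A <- partition_A(A)
  T_ <- ncol(A)
  if (T_ < 2L) abort("Flexibility is undefined for fewer than 2 windows.")
  changes <- A[, -1L, drop = FALSE] != A[, -T_, drop = FALSE]
  rowMeans(changes)
}

#' Module allegiance matrix
#'
#' `P[i, j]` is the fraction of windows in which channels i and j share a
#' community; symmetric with a unit diagonal.
#'
#' @inheritParams temporal_flexibility
#' @return An `allegiance_matrix` (numeric N x N with class attribute).
#' @export
module_allegiance <- function(A) {
  A <- partition_A(A)
  T_ <- ncol(A)
  if (T_ < 1L) abort("At least one window is required.")
  P <- matrix(0, nrow(A), nrow(A))
  for (t in seq_len(T_)) P <- P + outer(A[, t], A[, t], "==")
  P <- P / T_
  dimnames(P) <- list(rownames(A), rownames(A))
  class(P) <- c("allegiance_matrix", class(P))
  P
}

#' Integration and recruitment per region
#'
#' System-pair interaction `I[k1, k2] = sum_{i in C_k1, j in C_k2} P_ij /
#' (|C_k1| |C_k2|)` computed from the module allegiance matrix, with
#' channel regions (Brodmann areas or cortices) as systems. Recruitment
#' of a system is `I[k, k]` (self-pairs included by default, where
#' `P_ii = 1`); integration of a system is the mean interaction with all
#' other systems, divided by the grand mean of off-diagonal allegiance
#' (set `normalize = FALSE` for the raw mean interaction).
#'
#' @param P an [module_allegiance()] matrix (rows named by channel).
#' @param regions named list of channel-index vectors (one per system),
#'   e.g. from channel assignment at BA or cortex level.
#' @param include_self include i = j pairs in recruitment (the literal
#'   formula); `FALSE` excludes them for sensitivity analysis.
#' @param normalize divide integration by the mean off-diagonal allegiance.
#' @return Tibble with columns `region`, `recruitment`, `integration`.
#' @export
integration_recruitment <- function(P, regions, include_self = TRUE,
                                    normalize = TRUE) {
  P <- unclass(P)
  if (length(regions) < 2L) {
    abort("Integration needs at least two regions.")
  }
  if (any(!lengths(regions))) abort("Empty region.")
  K <- length(regions)
  I_mat <- matrix(0, K, K)
  for (k1 in seq_len(K)) {
    for (k2 in seq_len(K)) {
      block <- P[regions[[k1]], regions[[k2]], drop = FALSE]
      if (k1 == k2 && !include_self) {
        n <- length(regions[[k1]])
        I_mat[k1, k2] <- if (n > 1) (sum(block) - n) / (n^2 - n) else NA_real_
      } else {
        I_mat[k1, k2] <- mean(block)
      }
    }
  }
  integ <- vapply(seq_len(K), function(k) mean(I_mat[k, -k]), 0)
  if (normalize) {
    off <- P[row(P) != col(P)]
    pbar <- mean(off)
    integ <- if (pbar > 0) integ / pbar else rep(NA_real_, K)
  }
  tibble(
    region = names(regions),
    recruitment = diag(I_mat),
    integration = integ
  )
}

#' Node strength
#'
#' Average functional connection weight of each channel: the mean of its
#' off-diagonal coherence weights over all incident edges (set
#' `within = TRUE` with a region restriction upstream for the
#' within-region variant).
#'
#' @param gamma_mat symmetric coherence adjacency matrix.
#' @return Named numeric vector of per-channel strengths.
#' @export
node_strength <- function(gamma_mat) {
  n <- nrow(gamma_mat)
  if (n < 2L) abort("Strength needs at least 2 channels.")
  (rowSums(gamma_mat) - diag(gamma_mat)) / (n - 1)
}

# Total (summed) off-diagonal strength, the denominator of the walker's
# transition probabilities.
strength_sum <- function(gamma_mat) {
  rowSums(gamma_mat) - diag(gamma_mat)
}

#' Search information between nodes
#'
#' Bits a random walker needs to follow the shortest path from `i` to
#' `j`: `S(i -> j) = -log2 prod (Gamma_uv / s_u)` along the path, where
#' `s_u` is node u's total off-diagonal strength and shortest paths are
#' measured on edge lengths `-log(Gamma_uv)`. `S(i, i) = 0`; equal-length
#' shortest paths are averaged over; disconnected pairs are `Inf`
#' (excluded, with a logged count, when averaged into per-channel values).
#'
#' @param gamma_mat symmetric nonnegative coherence matrix; zero entries
#'   are non-edges.
#' @param from,to optional node indices; both given returns one value,
#'   otherwise the full N x N matrix of `S(i -> j)`.
#' @return Single numeric value or an N x N matrix in bits (asymmetric).
#' @export
search_information <- function(gamma_mat, from = NULL, to = NULL) {
  g <- gamma_mat
  diag(g) <- 0
  n <- nrow(g)
  gr <- igraph::graph_from_adjacency_matrix(g, mode = "undirected", weighted = TRUE)
  w <- igraph::E(gr)$weight
  s_tot <- strength_sum(gamma_mat)
  lens <- -log(w)
  one_source <- function(i) {
    out <- rep(Inf, n)
    out[i] <- 0
    res <- suppressWarnings(
      igraph::all_shortest_paths(gr, from = i, weights = lens)$vpaths
    )
    # group tied geodesics by endpoint, average S over ties
    ends <- vapply(res, function(p) as.integer(p[length(p)]), 1L)
    sbits <- vapply(res, function(p) {
      v <- as.integer(p)
      if (length(v) < 2L) {
        return(0)
      }
      steps <- cbind(v[-length(v)], v[-1L])
      -sum(log2(g[steps] / s_tot[steps[, 1]]))
    }, 0)
    agg <- tapply(sbits, ends, mean)
    out[as.integer(names(agg))] <- agg
    out[i] <- 0
    out
  }
  if (!is.null(from) && !is.null(to)) {
    return(one_source(from)[to])
  }
  S <- t(vapply(seq_len(n), one_source, numeric(n)))
  dimnames(S) <- dimnames(gamma_mat)
  S
}

# Per-channel search information: mean of S(i -> j) over reachable j != i.
channel_search_information <- function(gamma_mat) {
  S <- search_information(gamma_mat)
  diag(S) <- NA
  n_inf <- sum(is.infinite(S), na.rm = TRUE)
  if (n_inf > 0) {
    inform(sprintf(
      "%d disconnected node pair(s) excluded from search-information averages.",
      n_inf
    ))
    S[is.infinite(S)] <- NA
  }
  rowMeans(S, na.rm = TRUE)
}

region_feature_rows <- function(chan_val, members, metric, band) {
  tibble(
    metric = metric,
    region = names(members),
    band = band,
    value = vapply(members, function(ix) mean(chan_val[ix]), 0)
  )
}

#' Functional-network features for one band
#'
#' Computes, for a single band, the six-feature family of a recording:
#' region-averaged node strength and search information from the static
#' (whole-recording) coherence network, and temporal flexibility,
#' integration and recruitment from the windowed networks via the
#' consensus partition matrix and module allegiance. Band power comes
#' from [band_power_features()]; [extract_features()] combines both.
#'
#' @inheritParams coherence_matrix
#' @param band one row of [eeg_bands()] or a band name.
#' @param map a [load_ba_map()]; `NULL` loads the fixture.
#' @param level `"ba"` or `"cortex"` aggregation.
#' @param mask artifact mask of rejected 1-s windows.
#' @param n_reps,resolution,seed,max_iter consensus-partition settings.
#' @return Tibble in the standard feature layout (`metric`, `region`,
#'   `band`, `feature`, `value` plus identifiers).
#' @export
network_features <- function(rec, band, map = NULL, level = c("ba", "cortex"),
                             mask = NULL, n_reps = 100, resolution = 1,
                             seed = 1, max_iter = 50) {
  level <- match.arg(level)
  if (is.character(band)) band <- eeg_bands(band)
  assignment <- assign_brodmann(rec, map)
  members <- region_members(assignment, level)
  gamma_static <- coherence_matrix(rec, band)
  stack <- windowed_networks(rec, band, mask = mask)
  A <- build_partition_matrix(stack,
    n_reps = n_reps, resolution = resolution,
    seed = seed, max_iter = max_iter
  )
  P <- module_allegiance(A)
  ir <- integration_recruitment(P, members)
  rows <- bind_rows(
    region_feature_rows(node_strength(gamma_static), members, "strength", band$band),
    region_feature_rows(
      channel_search_information(gamma_static), members,
      "search_information", band$band
    ),
    region_feature_rows(
      temporal_flexibility(A), members, "flexibility",
      band$band
    ),
    tibble(
      metric = "integration", region = ir$region, band = band$band,
      value = ir$integration
    ),
    tibble(
      metric = "recruitment", region = ir$region, band = band$band,
      value = ir$recruitment
    )
  )
  rows %>%
    mutate(
      feature = paste(.data$metric, .data$region, .data$band, sep = "|"),
      subject_id = rec$subject_id, trial_id = rec$trial_id, task = rec$task
    ) %>%
    select(
      "subject_id", "trial_id", "task", "metric", "region", "band",
      "feature", "value"
    )
}

#' All features of a preprocessed recording
#'
#' The full per-trial feature vector: for every requested band, the five
#' functional-network metrics ([network_features()]) plus spectral band
#' power, aggregated at BA level (84 features per metric family with the
#' full fixture montage) or cortex level (96 features in total across the
#' six families). Ordering is deterministic: metric, then region, then
#' band.
#'
#' @inheritParams network_features
#' @param bands band table from [eeg_bands()].
#' @return Feature tibble, one row per (metric, region, band).
#' @export
extract_features <- function(rec, bands = eeg_bands(), map = NULL,
                             level = c("ba", "cortex"), mask = NULL,
                             n_reps = 100, resolution = 1, seed = 1,
                             max_iter = 50) {
  level <- match.arg(level)
  psd <- compute_psd(rec, mask = mask)
  net <- purrr::map(seq_len(nrow(bands)), function(b) {
    network_features(rec, bands[b, ],
      map = map, level = level, mask = mask,
      n_reps = n_reps, resolution = resolution,
      seed = seed + (b - 1L), max_iter = max_iter
    )
  })
  out <- bind_rows(
    bind_rows(net),
    band_power_features(psd, bands = bands, map = map, level = level)
  )
  metric_order <- c(
    "strength", "search_information", "flexibility",
    "integration", "recruitment", "psd"
  )
  region_order <- unique(out$region)
  out %>%
    mutate(
      metric = factor(.data$metric, levels = metric_order),
      region = factor(.data$region, levels = region_order),
      band = factor(.data$band, levels = bands$band)
    ) %>%
    arrange(.data$metric, .data$region, .data$band) %>%
    mutate(
      metric = as.character(.data$metric),
      region = as.character(.data$region),
      band = as.character(.data$band)
    )
}

#' Pivot a long feature tibble to one row per trial
#'
#' @param features long feature tibble from [extract_features()] (possibly
#'   several trials bound together).
#' @return Wide tibble keyed by `subject_id`, `trial_id`, `task` with one
#'   column per feature name.
#' @export
features_wide <- function(features) {
  features %>%
    select("subject_id", "trial_id", "task", "feature", "value") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}
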