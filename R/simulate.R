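#' Simulate a multichannel EEG recording with coupled source groups
#'
#' Generates channels as independent Gaussian noise plus band-limited
#' shared sources: each source group imposes a band-passed white-noise
#' source on its member channels at the stated coupling during its active
#' 1-s windows. Groups whose membership changes across windows induce
#' time-varying community structure, the regime the dynamic-network
#' features are designed to detect. Deterministic per seed.
#'
#' @param channels channel labels (defaults to the first 16 fixture
#'   labels); group members must be a subset.
#' @param rate sampling rate in Hz (500, the recording regime emulated).
#' @param duration_s recording length in seconds.
#' @param groups list of source groups, each a list with `channels`
#'   (member labels), `band` (name or c(lo, hi) Hz), `coupling` in
#'   `[0, 1]`, and optional `windows` (integer 1-s window numbers the
#'   group is active in; `NULL` = all).
#' @param noise_sd independent channel noise SD in µV.
#' @param amplitude source SD in µV before coupling.
#' @param seed integer seed.
#' @inheritParams new_recording
#' @return An [new_recording()] object.
#' @export
simulate_recording <- function(channels = NULL, rate = 500, duration_s = 10,
                               groups = list(), noise_sd = 1, amplitude = 1,
                               seed = 1, subject_id = "S1", trial_id = "T1",
                               task = "MB2") {
  if (is.null(channels)) {
    channels <- names(load_ba_map()$channel_ba)[1:16]
  }
  if (!length(channels)) abort("Empty montage.")
  n_chan <- length(channels)
  n_time <- round(duration_s * rate)
  win_len <- round(rate) # 1-s windows
  n_win <- n_time %/% win_len
  with_seed(seed, {
    samples <- matrix(rnorm(n_chan * n_time, sd = noise_sd), n_chan, n_time)
    for (grp in groups) {
      band <- grp$band
      if (is.character(band)) {
        bb <- eeg_bands(band)
        band <- c(bb$lo, bb$hi)
      }
      coupling <- grp$coupling
      if (coupling < 0 || coupling > 1) abort("Coupling must be in [0, 1].")
      members <- match_channels(channels, grp$channels)
      if (anyNA(members)) {
        abort(paste0(
          "Group member(s) not in the montage: ",
          paste(grp$channels[is.na(members)], collapse = ", ")
        ))
      }
      src <- rnorm(n_time)
      bf <- signal::butter(4, pmin(band / (rate / 2), 0.99), "pass")
      src <- signal::filtfilt(bf, src)
      src <- src / sd(src) * amplitude
      wins <- grp$windows
      if (is.null(wins)) wins <- seq_len(n_win)
      active <- rep(FALSE, n_time)
      for (w in wins) active[((w - 1) * win_len + 1):min(w * win_len, n_time)] <- TRUE
      mix <- coupling * src[active]
      for (ch in members) {
        samples[ch, active] <- (1 - coupling) * samples[ch, active] + mix
      }
    }
    new_recording(samples, rate, channels,
      subject_id = subject_id, trial_id = trial_id, task = task
    )
  })
}

#' Simulate performance and workload outcomes for a feature table
#'
#' Emulates the study's outcome scales: performance is a linear
#' combination of features plus a per-subject random intercept and noise,
#' clipped to `[0, 100]`; workload is the sum of six questionnaire
#' domains, each generated on the 1-20 scale from a shared latent linear
#' predictor, so the total lies in `[6, 120]`. Outcomes go missing
#' completely at random at the stated rate (mirroring the differing
#' per-model sample sizes seen with real trials).
#'
#' @param features wide feature tibble ([features_wide()]): one row per
#'   trial with a `subject_id` column.
#' @param true_beta named vector of coefficients on feature columns
#'   (names must exist in `features`).
#' @param intercept baseline added to the linear predictor
#'   (performance scale).
#' @param subject_sd SD of the per-subject random intercept.
#' @param noise_sd residual SD.
#' @param missing_prob probability an outcome is missing.
#' @param seed integer seed.
#' @return `features` with `performance` and `workload` columns appended.
#' @export
simulate_outcomes <- function(features, true_beta = numeric(),
                              intercept = 50, subject_sd = 5, noise_sd = 2,
                              missing_prob = 0, seed = 1) {
  stopifnot(missing_prob >= 0, missing_prob <= 1)
  bad <- setdiff(names(true_beta), colnames(features))
  if (length(bad)) {
    abort(paste0("Unknown feature(s) in true_beta: ", paste(bad, collapse = ", ")))
  }
  n <- nrow(features)
  subj <- as.character(features$subject_id)
  with_seed(seed, {
    b <- setNames(rnorm(length(unique(subj)), sd = subject_sd), unique(subj))
    lin <- rep(0, n)
    for (nm in names(true_beta)) lin <- lin + true_beta[[nm]] * features[[nm]]
    eta <- intercept + lin + b[subj]
    performance <- pmin(pmax(eta + rnorm(n, sd = noise_sd), 0), 100)
    # six SURG-TLX domains on 1..20 from a latent predictor centred at 10
    domain_eta <- 10 + (lin + b[subj]) / 6
    workload <- rowSums(vapply(seq_len(6), function(d) {
      pmin(pmax(round(domain_eta + rnorm(n, sd = noise_sd)), 1), 20)
    }, numeric(n)))
    if (missing_prob > 0) {
      performance[runif(n) < missing_prob] <- NA
      workload[runif(n) < missing_prob] <- NA
    }
    features$performance <- performance
    features$workload <- workload
    features
  })
}

#' Simulate a plain per-trial feature table
#'
#' Standard-normal feature columns for model-layer simulations
#' (parameter recovery, selection behaviour) without running the signal
#' pipeline.
#'
#' @param n_subjects,trials_per_subject design size; `trials_per_subject`
#'   may be a vector (recycled) for unbalanced designs.
#' @param feature_names names of the feature columns to generate.
#' @param seed integer seed.
#' @return Wide tibble with `subject_id`, `trial_id`, `task` and features.
#' @export
simulate_feature_table <- function(n_subjects = 26, trials_per_subject = 4,
                                   feature_names = paste0("f", 1:10),
                                   seed = 1) {
  tps <- rep(trials_per_subject, length.out = n_subjects)
  subj <- rep(sprintf("S%02d", seq_len(n_subjects)), tps)
  n <- length(subj)
  with_seed(seed, {
    out <- tibble(
      subject_id = subj,
      trial_id = paste0("T", unlist(lapply(tps, seq_len))),
      task = "MB2"
    )
    for (nm in feature_names) out[[nm]] <- rnorm(n)
    out
  })
}

#' Simulate a small study cohort with membership-switching trials
#'
#' Generates per-subject, per-trial recordings in which a band-limited
#' coupled source group either stays on the same channels throughout
#' (stable trials) or hands half its members over to another channel set
#' halfway through (switching trials, odd trial numbers). Switching
#' raises the temporal flexibility of the swapped channels, giving a
#' trial-varying dynamic-network feature that outcomes can be tied to.
#'
#' @param n_subjects,trials_per_subject cohort size.
#' @param duration_s trial length in seconds (an even number of 1-s
#'   windows).
#' @param band source band name.
#' @param coupling source coupling in `[0, 1]`.
#' @param noise_sd independent channel noise SD (µV).
#' @param seed master seed; trials get derived seeds.
#' @return List with `recordings` (list of [new_recording()] objects),
#'   `trials` (tibble: `subject_id`, `trial_id`, `task`, `switching`),
#'   `stable_channels` and `switching_channels` (label vectors).
#' @export
simulate_study <- function(n_subjects = 8, trials_per_subject = 4,
                           duration_s = 12, band = "alpha", coupling = 0.9,
                           noise_sd = 1, seed = 1) {
  ch <- c(
    "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "FC1", "FC2", "CP1", "CP2", "PO3", "PO4", "T7", "T8"
  )
  n_win <- floor(duration_s)
  half <- n_win %/% 2
  recordings <- list()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(trials_per_subject)) {
      switching <- tr %% 2 == 1
      groups <- if (switching) {
        list(
          list(
            channels = c("F3", "F4", "C3", "C4"), band = band,
            coupling = coupling, windows = seq_len(half)
          ),
          list(
            channels = c("F3", "F4", "P3", "P4"), band = band,
            coupling = coupling, windows = (half + 1):n_win
          )
        )
      } else {
        list(list(
          channels = c("F3", "F4", "C3", "C4"), band = band,
          coupling = coupling, windows = seq_len(n_win)
        ))
      }
      recordings[[length(recordings) + 1L]] <- simulate_recording(
        channels = ch, duration_s = duration_s, groups = groups,
        noise_sd = noise_sd,
        seed = seed + 1000L * s + tr,
        subject_id = sprintf("S%02d", s), trial_id = paste0("T", tr),
        task = "MB2"
      )
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = sprintf("S%02d", s), trial_id = paste0("T", tr),
        task = "MB2", switching = switching
      )
    }
  }
  list(
    recordings = recordings, trials = bind_rows(rows),
    stable_channels = c("F3", "F4"),
    switching_channels = c("C3", "C4", "P3", "P4")
  )
}

#' Library of toy graphs with known metric values
#'
#' Deterministic fixtures used to check the network metrics against
#' closed-form or planted expectations: a 3-node unit-weight path (1 bit
#' of search information end to end), a unit-weight star (2 bits leaf to
#' leaf across 4 leaves), two disconnected 4-cliques (the modularity
#' optimum splits them), a single clique (one community) and a planted
#' 3-block weighted network.
#'
#' @param n_per_block nodes per block of the planted-partition graph.
#' @param within,between planted within-/between-block weights.
#' @return Named list; each element has `gamma` (adjacency) and
#'   `expected` (a list of known values).
#' @export
make_toy_graphs <- function(n_per_block = 6, within = 0.8, between = 0.1) {
  path3 <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  path3["A", "B"] <- path3["B", "A"] <- 1
  path3["B", "C"] <- path3["C", "B"] <- 1
  diag(path3) <- 1

  star <- matrix(0, 5, 5, dimnames = rep(list(c("hub", paste0("L", 1:4))), 2))
  star[1, 2:5] <- star[2:5, 1] <- 1
  diag(star) <- 1

  clique <- function(n) {
    m <- matrix(1, n, n)
    m
  }
  two_cliques <- rbind(
    cbind(clique(4), matrix(0, 4, 4)),
    cbind(matrix(0, 4, 4), clique(4))
  )
  dimnames(two_cliques) <- rep(list(paste0("n", 1:8)), 2)

  blocks <- matrix(between, 3 * n_per_block, 3 * n_per_block)
  for (b in 1:3) {
    ix <- ((b - 1) * n_per_block + 1):(b * n_per_block)
    blocks[ix, ix] <- within
  }
  diag(blocks) <- 1
  dimnames(blocks) <- rep(list(paste0("n", seq_len(3 * n_per_block))), 2)

  list(
    path3 = list(
      gamma = path3,
      expected = list(s_ac_bits = 1, s_ca_bits = 1)
    ),
    star4 = list(
      gamma = star,
      expected = list(s_leaf_leaf_bits = 2)
    ),
    two_cliques = list(
      gamma = two_cliques,
      expected = list(membership = rep(1:2, each = 4))
    ),
    single_clique = list(
      gamma = `dimnames<-`(clique(5), rep(list(paste0("n", 1:5)), 2)),
      expected = list(n_communities = 1)
    ),
    planted_blocks = list(
      gamma = blocks,
      expected = list(membership = rep(1:3, each = n_per_block))
    )
  )
}
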