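#' Run the full evaluation pipeline
#'
#' Orchestrates preprocessing, feature extraction and the statistical
#' layer for a set of recordings with matched outcomes. Approach A fits
#' subject-blocked 7-fold cross-validated forward selection feeding a
#' random-intercept model; approaches B and C run the L1-penalized mixed
#' model after an LOF screen, B on cortex-aggregated full-montage
#' features and C on the reduced 32-channel montage (both constraints
#' are enforced).
#'
#' @param recordings list of [new_recording()] objects (or file paths
#'   loadable by [load_recording()]), one per trial, each carrying
#'   `subject_id`/`trial_id`/`task`.
#' @param outcomes tibble with `subject_id`, `trial_id`, `task` and the
#'   outcome columns to be modelled.
#' @param outcome outcome column name (`"performance"` or `"workload"`).
#' @param approach `"A"`, `"B"` or `"C"`.
#' @param montage `"full"` or `"reduced32"` (approach C forces
#'   `"reduced32"`).
#' @param level `"ba"` or `"cortex"` (approaches B and C force
#'   `"cortex"`).
#' @param bands band table from [eeg_bands()].
#' @param map a [load_ba_map()]; `NULL` loads the fixture.
#' @param preprocess run the five-step decontamination chain first.
#' @param n_reps Louvain repetitions per consensus iteration.
#' @param cv_k folds for approach A's subject-blocked cross-validation
#'   (7 in the emulated design; capped at the number of subjects).
#' @param seed master seed for every stochastic step.
#' @param ... further arguments to [preprocess_recording()].
#' @return A `pipeline_result`: list with `features` (long tibble),
#'   `table` (wide, joined with outcomes), `fit`, `config`.
#' @export
run_pipeline <- function(recordings, outcomes, outcome = "workload",
                         approach = c("A", "B", "C"),
                         montage = c("full", "reduced32"),
                         level = c("ba", "cortex"), bands = eeg_bands(),
                         map = NULL, preprocess = TRUE, n_reps = 100,
                         cv_k = 7, seed = 1, ...) {
  approach <- match.arg(approach)
  montage <- match.arg(montage)
  level <- match.arg(level)
  if (approach == "C" && montage != "reduced32") {
    abort("Approach C requires the reduced 32-channel montage.")
  }
  if (approach %in% c("B", "C") && level != "cortex") {
    abort(sprintf("Approach %s requires cortex-level aggregation.", approach))
  }
  feats <- purrr::imap(recordings, function(rec, i) {
    if (is.character(rec)) rec <- load_recording(rec)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("[%s, trial %s/%s] %s", name, rec$subject_id,
          rec$trial_id, conditionMessage(e)
        ))
      })
    }
    if (montage == "reduced32") rec <- stage("montage", reduced_montage(rec))
    mask <- NULL
    if (preprocess) {
      pp <- stage("preprocess", preprocess_recording(rec, ...))
      rec <- pp$recording
      mask <- pp$mask
    }
    stage("features", extract_features(rec,
      bands = bands, map = map,
      level = level, mask = mask, n_reps = n_reps, seed = seed
    ))
  })
  features <- bind_rows(feats)
  wide <- features_wide(features)
  tab <- left_join(wide, outcomes, by = c("subject_id", "trial_id", "task"))
  predictors <- setdiff(
    colnames(wide), c("subject_id", "trial_id", "task")
  )
  fit <- if (approach == "A") {
    k_use <- min(cv_k, length(unique(tab$subject_id)))
    forward_select_cv(tab, outcome, predictors, k = k_use, seed = seed)
  } else {
    scr <- lof_screen(tab, feature_cols = predictors)
    glmm_lasso(scr$table, outcome, predictors, seed = seed)
  }
  structure(
    list(
      features = features, table = tab, fit = fit,
      config = list(
        approach = approach, montage = montage, level = level,
        outcome = outcome, bands = bands$band, n_reps = n_reps, seed = seed
      )
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> approach %s (%s montage, %s level), outcome %s\n",
    x$config$approach, x$config$montage, x$config$level, x$config$outcome
  ))
  cat(sprintf(
    "  %d trials x %d features\n", nrow(x$table),
    length(unique(x$features$feature))
  ))
  print(x$fit)
  invisible(x)
}
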