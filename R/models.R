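#' Efron's pseudo-R-squared
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: the fraction of outcome
#' variation explained by the fitted values.
#'
#' @param y observed outcomes.
#' @param yhat fitted values of equal length.
#' @return Single numeric value (1 for a perfect fit, 0 for the mean).
#' @export
efron_pseudo_r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` differ in length.")
  if (length(y) < 2L) abort("Need at least 2 observations.")
  ss <- sum((y - mean(y))^2)
  if (ss == 0) abort("Outcome has zero variance.")
  1 - sum((y - yhat)^2) / ss
}

#' Mean absolute and root-mean-squared error
#' @inheritParams efron_pseudo_r2
#' @return Single numeric value.
#' @export
mae <- function(y, yhat) mean(abs(y - yhat))

#' @rdname mae
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper over the t-based Pearson test, the convention used for the
#' age/performance/workload correlations (two-sided, alpha = 0.05).
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return Tibble with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` differ in length.")
  if (length(x) < 3L) abort("Need at least 3 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Inputs must be finite.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input.")
  ct <- cor.test(x, y, alternative = "two.sided", method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Sidak multiple-testing adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons (default: `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (m < 1) abort("`m` must be at least 1.")
  pmin(1, 1 - (1 - p)^m)
}

# Feature names carry "|" separators which formulas cannot hold; model
# internally on sanitized names and translate back for reporting.
sanitize_frame <- function(table, outcome, predictors, subject_col) {
  missing_cols <- setdiff(c(outcome, predictors, subject_col), colnames(table))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  key <- if (length(predictors)) paste0(".x", seq_along(predictors)) else character()
  df <- data.frame(
    .y = table[[outcome]],
    .subject = factor(table[[subject_col]])
  )
  for (i in seq_along(predictors)) df[[key[i]]] <- table[[predictors[i]]]
  keep <- stats::complete.cases(df)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf(
      "Dropping %d row(s) with missing outcome or predictors.", n_drop
    ))
  }
  df <- df[keep, , drop = FALSE]
  df$.subject <- droplevels(df$.subject)
  list(df = df, key = setNames(predictors, key), n_dropped = n_drop)
}

lmm_formula <- function(key) {
  rhs <- if (length(key)) paste(names(key), collapse = " + ") else "1"
  as.formula(paste("`.y` ~", rhs, "+ (1 | .subject)"))
}

#' Linear random-intercept model of an outcome
#'
#' Fits `outcome ~ predictors + (1 | subject)` by REML, reporting fixed
#' effects with Wald (normal) p-values, a likelihood-ratio test of the
#' subject random intercept with the half-chi-squared boundary
#' correction, Efron's pseudo-R-squared, MAE and RMSE on the (conditional)
#' fitted values. Rows with missing outcome or predictors are dropped
#' with a message.
#'
#' @param table per-trial data frame or tibble holding outcome, predictor
#'   and subject columns (e.g. [features_wide()] joined with outcomes).
#' @param outcome outcome column name (`"performance"` or `"workload"`).
#' @param predictors character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param subject_col subject identifier column.
#' @return A `workload_fit`: use [tidy()] for the coefficient table and
#'   [glance()] for fit statistics (`pseudo_r2`, `mae`, `rmse`, `n_obs`,
#'   `re_sd`, `re_p`, `singular`).
#' @export
fit_random_intercept <- function(table, outcome, predictors = character(),
                                 subject_col = "subject_id") {
  sf <- sanitize_frame(table, outcome, predictors, subject_col)
  df <- sf$df
  tab <- table(df$.subject)
  if (length(tab) < 2L || sum(tab >= 2L) < 2L) {
    abort("Need at least 2 subjects with at least 2 observations each.")
  }
  if (nrow(df) <= length(predictors) + 1L) {
    abort("More fixed effects than observations.")
  }
  fit <- suppressMessages(lme4::lmer(lmm_formula(sf$key), data = df, REML = TRUE,
    control = lme4::lmerControl(check.scaleX = "ignore")
  ))
  singular <- lme4::isSingular(fit)
  cf <- summary(fit)$coefficients
  terms <- rownames(cf)
  terms[terms %in% names(sf$key)] <- sf$key[terms[terms %in% names(sf$key)]]
  coefs <- tibble(
    term = terms,
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = 2 * pnorm(-abs(cf[, "t value"]))
  )
  # boundary-corrected LRT for the variance component
  ml1 <- suppressMessages(lme4::refitML(fit))
  ml0 <- stats::lm(
    as.formula(paste(
      "`.y` ~",
      if (length(sf$key)) paste(names(sf$key), collapse = " + ") else "1"
    )),
    data = df
  )
  lrt <- max(0, 2 * (as.numeric(logLik(ml1)) - as.numeric(logLik(ml0))))
  re_p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  yhat <- stats::fitted(fit)
  y <- df$.y
  structure(
    list(
      model = fit, coefficients = coefs, outcome = outcome,
      predictors = predictors,
      re_sd = sqrt(unname(lme4::VarCorr(fit)$.subject[1])),
      re_p = re_p, singular = singular,
      pseudo_r2 = efron_pseudo_r2(y, yhat),
      mae = mae(y, yhat), rmse = rmse(y, yhat),
      n_obs = nrow(df), n_subjects = nlevels(df$.subject),
      n_dropped = sf$n_dropped
    ),
    class = "workload_fit"
  )
}

#' @export
print.workload_fit <- function(x, ...) {
  cat(sprintf(
    "<workload_fit> %s ~ %d predictor(s) + (1 | subject), n = %d\n",
    x$outcome, length(x$predictors), x$n_obs
  ))
  print(as.data.frame(tidy(x)), digits = 3)
  cat(sprintf(
    "pseudo-R2 = %.3f  MAE = %.3f  RMSE = %.3f  subject SD = %.3f (LRT p = %.3g)%s\n",
    x$pseudo_r2, x$mae, x$rmse, x$re_sd, x$re_p,
    if (x$singular) "  [singular fit]" else ""
  ))
  invisible(x)
}

#' @export
tidy.workload_fit <- function(x, ...) x$coefficients

#' @export
glance.workload_fit <- function(x, ...) {
  tibble(
    pseudo_r2 = x$pseudo_r2, mae = x$mae, rmse = x$rmse,
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    re_sd = x$re_sd, re_p = x$re_p, singular = x$singular
  )
}

subject_folds <- function(subjects, k, seed = 1) {
  u <- unique(subjects)
  if (k > length(u)) {
    abort(sprintf("k = %d folds exceed the %d available subjects.", k, length(u)))
  }
  shuffled <- with_seed(seed, sample(u))
  fold_of <- setNames(rep(seq_len(k), length.out = length(u)), shuffled)
  unname(fold_of[as.character(subjects)])
}

lmm_bic <- function(df, key) {
  fit <- try(
    suppressMessages(suppressWarnings(
      lme4::lmer(lmm_formula(key), data = df, REML = FALSE,
        control = lme4::lmerControl(calc.derivs = FALSE,
          check.conv.singular = "ignore", check.scaleX = "ignore"
        )
      )
    )),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    return(Inf)
  }
  BIC(fit)
}

#' Subject-blocked cross-validated forward selection
#'
#' Splits subjects (never rows) into `k` folds; within each fold's
#' training set, runs forward selection on the random-intercept model,
#' adding at each step the predictor that most decreases the model BIC
#' and stopping when BIC no longer decreases. Predictors selected in at
#' least `keep_threshold` folds form the final model, refit on all data
#' with Sidak-adjusted p-values (`m` = number of kept predictors).
#'
#' @inheritParams fit_random_intercept
#' @param predictors candidate predictor columns.
#' @param k number of folds (7 in the emulated design); at most the number
#'   of subjects.
#' @param keep_threshold minimum number of folds a variable must be
#'   selected in (2 in the emulated design).
#' @param max_steps cap on forward-selection steps per fold.
#' @param seed seed for the subject shuffle.
#' @return A `forward_cv` list: `selected` (kept predictors),
#'   `counts` (fold-selection counts), `fit` (final `workload_fit`, `NULL`
#'   when nothing was kept) whose tidy() table carries `p.adjusted`.
#' @export
forward_select_cv <- function(table, outcome, predictors,
                              subject_col = "subject_id", k = 7,
                              keep_threshold = 2, max_steps = 10, seed = 1) {
  sf <- sanitize_frame(table, outcome, predictors, subject_col)
  df <- sf$df
  folds <- subject_folds(df$.subject, k, seed = seed)
  keys <- names(sf$key)
  counts <- setNames(rep(0L, length(predictors)), predictors)
  for (f in seq_len(k)) {
    train <- df[folds != f, , drop = FALSE]
    sel <- character()
    cur_bic <- lmm_bic(train, sf$key[character()])
    remaining <- keys
    for (step in seq_len(min(max_steps, length(keys)))) {
      bics <- vapply(remaining, function(cand) {
        lmm_bic(train, sf$key[c(sel, cand)])
      }, 0)
      if (!length(bics) || min(bics) >= cur_bic) break
      best <- remaining[which.min(bics)]
      sel <- c(sel, best)
      remaining <- setdiff(remaining, best)
      cur_bic <- min(bics)
    }
    counts[sf$key[sel]] <- counts[sf$key[sel]] + 1L
  }
  kept <- names(counts)[counts >= keep_threshold]
  fit <- NULL
  if (length(kept)) {
    fit <- fit_random_intercept(table, outcome, kept, subject_col = subject_col)
    m <- length(kept)
    fit$coefficients$p.adjusted <- ifelse(
      fit$coefficients$term == "(Intercept)",
      fit$coefficients$p.value,
      sidak_adjust(fit$coefficients$p.value, m)
    )
  }
  structure(
    list(selected = kept, counts = counts, fit = fit, k = k,
      keep_threshold = keep_threshold
    ),
    class = "forward_cv"
  )
}

#' @export
print.forward_cv <- function(x, ...) {
  cat(sprintf(
    "<forward_cv> %d predictor(s) kept (selected in >= %d of %d folds)\n",
    length(x$selected), x$keep_threshold, x$k
  ))
  if (length(x$selected)) {
    for (s in x$selected) cat("  ", s, " (", x$counts[s], " folds)\n", sep = "")
    print(x$fit)
  }
  invisible(x)
}

#' L1-penalized mixed model (GLMM-LASSO style)
#'
#' Selects fixed effects by an L1 penalty while accounting for the
#' per-subject random intercept: for each lambda on the grid the fixed
#' effects are fit by coordinate-descent lasso with the current random
#' intercepts as an offset, and the variance components are re-estimated
#' from the residuals, alternating to convergence. Lambda is chosen by
#' BIC of the support-refit mixed model (cross-validation is available
#' via `choose = "cv"`); the selected support is refit unpenalized for
#' the reported estimates and p-values.
#'
#' @inheritParams fit_random_intercept
#' @param predictors candidate predictor columns.
#' @param lambda_grid decreasing penalty grid; `NULL` uses the glmnet path.
#' @param nlambda grid size when `lambda_grid` is `NULL`.
#' @param choose `"bic"` (default) or `"cv"` (subject-blocked deviance).
#' @param k folds for `choose = "cv"`.
#' @param max_alt alternations between lasso and variance steps.
#' @param seed seed for fold construction.
#' @return A `glmm_lasso_fit` (also a `workload_fit` when the support is
#'   non-empty): adds `lambda`, `support`, `path` (per-lambda support size
#'   and criterion). An all-empty path yields an empty model, not an error.
#' @export
glmm_lasso <- function(table, outcome, predictors,
                       subject_col = "subject_id", lambda_grid = NULL,
                       nlambda = 30, choose = c("bic", "cv"), k = 5,
                       max_alt = 10, seed = 1) {
  choose <- match.arg(choose)
  sf <- sanitize_frame(table, outcome, predictors, subject_col)
  df <- sf$df
  X <- as.matrix(df[, names(sf$key), drop = FALSE])
  colnames(X) <- names(sf$key)
  y <- df$.y
  subj <- df$.subject
  if (is.null(lambda_grid)) {
    lambda_grid <- glmnet::glmnet(X, y, nlambda = nlambda)$lambda
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fit_at_lambda <- function(lam) {
    b <- setNames(rep(0, nlevels(subj)), levels(subj))
    beta <- rep(0, ncol(X))
    for (it in seq_len(max_alt)) {
      gfit <- glmnet::glmnet(X, y - b[subj], lambda = lam)
      beta_new <- as.numeric(coef(gfit))[-1]
      resid <- y - as.numeric(predict(gfit, X))
      vc <- try(
        suppressMessages(suppressWarnings(
          lme4::lmer(r ~ 1 + (1 | s),
            data = data.frame(r = resid, s = subj), REML = TRUE,
            control = lme4::lmerControl(calc.derivs = FALSE,
              check.conv.singular = "ignore", check.scaleX = "ignore"
            )
          )
        )),
        silent = TRUE
      )
      if (inherits(vc, "try-error")) break
      b_new <- setNames(rep(0, nlevels(subj)), levels(subj))
      re <- lme4::ranef(vc)$s
      b_new[rownames(re)] <- re[, 1] + lme4::fixef(vc)[1]
      if (max(abs(beta_new - beta)) < 1e-6 && max(abs(b_new - b)) < 1e-6) {
        beta <- beta_new
        b <- b_new
        break
      }
      beta <- beta_new
      b <- b_new
    }
    which(beta != 0)
  }

  supports <- lapply(lambda_grid, fit_at_lambda)
  crit <- numeric(length(lambda_grid))
  if (choose == "bic") {
    for (i in seq_along(lambda_grid)) {
      crit[i] <- lmm_bic(df, sf$key[supports[[i]]])
    }
  } else {
    folds <- subject_folds(subj, k, seed = seed)
    for (i in seq_along(lambda_grid)) {
      key_i <- sf$key[supports[[i]]]
      errs <- vapply(seq_len(k), function(f) {
        tr <- df[folds != f, , drop = FALSE]
        te <- df[folds == f, , drop = FALSE]
        m <- try(
          suppressMessages(suppressWarnings(
            lme4::lmer(lmm_formula(key_i), data = tr, REML = FALSE,
              control = lme4::lmerControl(calc.derivs = FALSE,
                check.conv.singular = "ignore", check.scaleX = "ignore"
              )
            )
          )),
          silent = TRUE
        )
        if (inherits(m, "try-error")) {
          return(Inf)
        }
        pr <- predict(m, newdata = te, allow.new.levels = TRUE, re.form = NA)
        mean((te$.y - pr)^2)
      }, 0)
      crit[i] <- mean(errs)
    }
  }
  best <- which.min(crit)
  support_keys <- names(sf$key)[supports[[best]]]
  support <- unname(sf$key[support_keys])
  path <- tibble(
    lambda = lambda_grid,
    n_support = lengths(supports),
    criterion = crit
  )
  if (length(support)) {
    out <- fit_random_intercept(table, outcome, support, subject_col = subject_col)
    out$lambda <- lambda_grid[best]
    out$support <- support
    out$path <- path
    class(out) <- c("glmm_lasso_fit", class(out))
  } else {
    out <- structure(
      list(
        support = character(), lambda = lambda_grid[best], path = path,
        outcome = outcome, predictors = character(), coefficients = tibble(
          term = character(), estimate = numeric(), std.error = numeric(),
          statistic = numeric(), p.value = numeric()
        ),
        pseudo_r2 = NA_real_, mae = NA_real_, rmse = NA_real_,
        re_sd = NA_real_, re_p = NA_real_, singular = NA,
        n_obs = nrow(df), n_subjects = nlevels(subj), n_dropped = sf$n_dropped
      ),
      class = c("glmm_lasso_fit", "workload_fit")
    )
  }
  out
}

#' @export
print.glmm_lasso_fit <- function(x, ...) {
  cat(sprintf(
    "<glmm_lasso_fit> lambda = %.4g, support size %d\n",
    x$lambda, length(x$support)
  ))
  if (length(x$support)) NextMethod()
  invisible(x)
}

#' Local-outlier-factor screen
#'
#' Density-based outlier detection on the feature columns: the LOF score
#' of a row compares its local reachability density with that of its
#' `n_neighbors` nearest neighbours (ties included). With
#' `contamination = "auto"` rows scoring above 1.5 are removed (the
#' common cutoff); a numeric contamination removes at most that fraction,
#' highest scores first, among rows scoring above 1.
#'
#' @param table data frame of samples.
#' @param feature_cols columns to compute distances on (`NULL` = all
#'   numeric columns).
#' @param n_neighbors neighbourhood size (default 20, capped at n - 1).
#' @param contamination `"auto"` or a fraction in `[0, 1]`.
#' @return List with `table` (outliers removed), `outliers` (row indices
#'   of the input) and `scores`.
#' @export
lof_screen <- function(table, feature_cols = NULL, n_neighbors = 20,
                       contamination = "auto") {
  if (is.null(feature_cols)) {
    feature_cols <- colnames(table)[vapply(table, is.numeric, TRUE)]
  }
  Xs <- scale(as.matrix(table[, feature_cols, drop = FALSE]))
  Xs[, !is.finite(colSums(Xs))] <- 0
  n <- nrow(Xs)
  if (n <= n_neighbors) {
    if (n < 3L) abort("Too few rows for an LOF screen.")
    n_neighbors <- n - 1L
  }
  D <- as.matrix(dist(Xs))
  diag(D) <- Inf
  scores <- lof_scores(D, n_neighbors)
  out_idx <- integer()
  if (identical(contamination, "auto")) {
    out_idx <- which(scores > 1.5)
  } else {
    contamination <- as.numeric(contamination)
    if (contamination < 0 || contamination > 1) {
      abort("`contamination` must be in [0, 1] or \"auto\".")
    }
    n_out <- floor(contamination * n)
    if (n_out > 0) {
      cand <- order(scores, decreasing = TRUE)
      cand <- cand[scores[cand] > 1][seq_len(min(n_out, sum(scores > 1)))]
      out_idx <- sort(cand)
    }
  }
  if (length(out_idx)) {
    inform(sprintf("LOF screen removed %d of %d rows.", length(out_idx), n))
  }
  list(
    table = table[setdiff(seq_len(n), out_idx), , drop = FALSE],
    outliers = out_idx, scores = scores
  )
}

# Classic LOF with k-distance neighbourhoods including ties; duplicate
# points (zero reachability density on both sides) score 1 by convention.
lof_scores <- function(D, k) {
  n <- nrow(D)
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    srt <- sort(D[i, ])
    kdist[i] <- srt[k]
    nbrs[[i]] <- which(D[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    m <- mean(reach)
    lrd[i] <- if (m > 0) 1 / m else Inf
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ratio <- lrd[nbrs[[i]]] / lrd[i]
    ratio[is.nan(ratio)] <- 1 # Inf / Inf: duplicates
    scores[i] <- mean(ratio)
  }
  scores[is.nan(scores)] <- 1
  scores
}
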