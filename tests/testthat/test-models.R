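test_that("Efron pseudo-R2, MAE and RMSE behave at the boundaries", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(efron_pseudo_r2(y, y), 1)
  expect_equal(efron_pseudo_r2(y, rep(mean(y), 8)), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(y, y), 0)

  set.seed(2)
  yhat <- y + rnorm(8)
  expect_equal(
    efron_pseudo_r2(y, yhat),
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  )
  expect_error(efron_pseudo_r2(rep(1, 5), rnorm(5)), "variance")
  expect_error(efron_pseudo_r2(1:3, 1:4), "length")
})

test_that("MAE never exceeds RMSE", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(30)
    yhat <- rnorm(30)
    expect_lte(mae(y, yhat), rmse(y, yhat) + 1e-12)
  }
})

test_that("Pearson correlation matches the hand formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- pearson_with_p(x, y)
  expect_equal(out$r, r_hand)
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), df = 3))

  expect_error(pearson_with_p(rep(1, 5), y), "variance")
  expect_error(pearson_with_p(1:2, 1:2), "3 observations")
})

test_that("Sidak adjustment follows 1 - (1 - p)^m", {
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.05, m = 2), 1 - 0.95^2)
  expect_equal(sidak_adjust(0.05, m = 2), 0.0975)
  expect_equal(sidak_adjust(c(0.5, 0.9), m = 10), pmin(1, 1 - (1 - c(0.5, 0.9))^10))
  expect_error(sidak_adjust(0.05, m = 0), "at least 1")
})

test_that("random-intercept model recovers an injected fixed effect", {
  tb <- simulate_feature_table(
    n_subjects = 20, trials_per_subject = 10,
    feature_names = c("x"), seed = 101
  )
  tb <- simulate_outcomes(tb,
    true_beta = c(x = 2), subject_sd = 1,
    noise_sd = 0.5, seed = 102
  )
  fit <- fit_random_intercept(tb, "performance", "x")
  co <- tidy(fit)
  b <- co$estimate[co$term == "x"]
  se <- co$std.error[co$term == "x"]
  expect_lt(abs(b - 2), 2 * se)
  expect_lt(glance(fit)$re_p, 0.05) # subject variance is real by design
  expect_gt(glance(fit)$pseudo_r2, 0.5)
})

test_that("null predictors are rarely declared significant", {
  hits <- 0
  for (s in 1:60) {
    tb <- simulate_feature_table(
      n_subjects = 10, trials_per_subject = 4,
      feature_names = "x", seed = 1000 + s
    )
    tb <- simulate_outcomes(tb,
      true_beta = c(x = 0), subject_sd = 2,
      noise_sd = 2, seed = 2000 + s
    )
    fit <- fit_random_intercept(tb, "performance", "x")
    co <- tidy(fit)
    if (co$p.value[co$term == "x"] < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 60, 0.15)
})

test_that("degenerate designs error; missing outcomes are dropped with a count", {
  tb <- simulate_feature_table(n_subjects = 1, trials_per_subject = 5, seed = 1)
  tb$performance <- rnorm(5)
  expect_error(fit_random_intercept(tb, "performance", "f1"), "2 subjects")

  tb2 <- simulate_feature_table(n_subjects = 6, trials_per_subject = 5, seed = 2)
  tb2 <- simulate_outcomes(tb2, true_beta = c(f1 = 1), seed = 3)
  tb2$performance[c(2, 9)] <- NA
  expect_message(
    fit <- fit_random_intercept(tb2, "performance", "f1"),
    "Dropping 2"
  )
  expect_equal(fit$n_obs, 28)
})

test_that("cross-validation folds never split a subject", {
  tb <- simulate_feature_table(n_subjects = 14, trials_per_subject = 3, seed = 5)
  folds <- neuroload:::subject_folds(tb$subject_id, k = 7, seed = 9)
  per_subject <- tapply(folds, tb$subject_id, function(f) length(unique(f)))
  expect_true(all(per_subject == 1))
  expect_equal(sort(unique(folds)), 1:7)
  expect_error(neuroload:::subject_folds(tb$subject_id, k = 20), "exceed")
})

test_that("forward selection finds an injected predictor and reports Sidak p", {
  tb <- simulate_feature_table(
    n_subjects = 14, trials_per_subject = 6,
    feature_names = paste0("f", 1:8), seed = 7
  )
  tb <- simulate_outcomes(tb,
    true_beta = c(f3 = 3), subject_sd = 2,
    noise_sd = 2, seed = 8
  )
  sel <- forward_select_cv(tb, "performance", paste0("f", 1:8), k = 7, seed = 1)
  expect_true("f3" %in% sel$selected)
  co <- tidy(sel$fit)
  expect_true("p.adjusted" %in% colnames(co))
  nonint <- co[co$term != "(Intercept)", ]
  expect_true(all(nonint$p.adjusted >= nonint$p.value - 1e-12))
})

test_that("forward selection keeps few features under a null outcome", {
  # folds share most of their rows, so a noise feature that happens to fit
  # is often re-selected across folds; selected sets stay small but are
  # not reliably empty
  sizes <- integer(20)
  for (s in seq_along(sizes)) {
    tb <- simulate_feature_table(
      n_subjects = 14, trials_per_subject = 5,
      feature_names = paste0("f", 1:20), seed = 300 + s
    )
    tb <- simulate_outcomes(tb,
      true_beta = c(), subject_sd = 2, noise_sd = 3,
      seed = 400 + s
    )
    sel <- forward_select_cv(tb, "performance", paste0("f", 1:20),
      k = 7,
      seed = s
    )
    sizes[s] <- length(sel$selected)
  }
  expect_lte(mean(sizes) / 20, 0.15) # small fraction of the candidates
  expect_gte(mean(sizes <= 1), 0.4) # empty/singleton is the common case
})

test_that("GLMM-LASSO recovers a planted 3-feature support", {
  tb <- simulate_feature_table(
    n_subjects = 20, trials_per_subject = 10,
    feature_names = paste0("f", 1:50), seed = 7
  )
  tb <- simulate_outcomes(tb,
    true_beta = c(f1 = 2, f2 = -1.5, f3 = 1),
    subject_sd = 3, noise_sd = 2, seed = 8
  )
  gl <- suppressMessages(glmm_lasso(tb, "performance", paste0("f", 1:50), seed = 1))
  expect_true(all(c("f1", "f2", "f3") %in% gl$support))
  expect_lte(length(setdiff(gl$support, c("f1", "f2", "f3"))), 2)
})

test_that("extreme penalties give an empty model, none matches the unpenalized fit", {
  tb <- simulate_feature_table(
    n_subjects = 10, trials_per_subject = 8,
    feature_names = c("a", "b"), seed = 11
  )
  tb <- simulate_outcomes(tb,
    true_beta = c(a = 2, b = -1), subject_sd = 1,
    noise_sd = 1, seed = 12
  )
  empty <- glmm_lasso(tb, "performance", c("a", "b"), lambda_grid = 1e6)
  expect_length(empty$support, 0)
  expect_equal(nrow(tidy(empty)), 0)

  near0 <- glmm_lasso(tb, "performance", c("a", "b"), lambda_grid = 1e-8)
  ref <- fit_random_intercept(tb, "performance", c("a", "b"))
  expect_equal(
    tidy(near0)$estimate, tidy(ref)$estimate,
    tolerance = 0.02
  )
})

test_that("LOF flags a gross outlier and spares duplicates", {
  set.seed(19)
  tb <- tibble::tibble(a = rnorm(60, sd = 0.5), b = rnorm(60, sd = 0.5))
  tb$a[13] <- 15 # ~30 sigma away
  scr <- suppressMessages(lof_screen(tb, c("a", "b"), n_neighbors = 20))
  expect_true(13 %in% scr$outliers)
  expect_equal(scr$outliers[which.max(scr$scores[scr$outliers])], 13)

  none <- lof_screen(tb, c("a", "b"), contamination = 0)
  expect_length(none$outliers, 0)

  dup <- tibble::tibble(a = rep(1, 25), b = rep(2, 25))
  expect_length(lof_screen(dup, c("a", "b"))$outliers, 0)

  expect_error(lof_screen(tb[1:2, ], c("a", "b")), "Too few")
})

test_that("confidence intervals cover an injected effect at the nominal rate", {
  covered <- 0
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    tps <- 2 + (s %% 5) # unbalanced trials across simulations
    tb <- simulate_feature_table(
      n_subjects = 26, trials_per_subject = c(tps, 4, 3, 5),
      feature_names = "x", seed = 5000 + s
    )
    tb <- simulate_outcomes(tb,
      true_beta = c(x = 1.5), subject_sd = 2,
      noise_sd = 2, seed = 6000 + s
    )
    fit <- fit_random_intercept(tb, "performance", "x")
    co <- tidy(fit)
    b <- co$estimate[co$term == "x"]
    se <- co$std.error[co$term == "x"]
    if (abs(b - 1.5) <= 1.96 * se) covered <- covered + 1
  }
  expect_gte(covered, 90)
})
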