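toys <- make_toy_graphs()

test_that("flexibility matches the change-counting oracle exhaustively", {
  # worked rows
  expect_equal(unname(temporal_flexibility(rbind(c(1, 1, 1, 1, 1)))), 0)
  expect_equal(unname(temporal_flexibility(rbind(c(1, 2, 1, 2, 1)))), 1)
  expect_equal(unname(temporal_flexibility(rbind(c(1, 1, 2, 2, 3)))), 0.5)

  # every label sequence with T <= 5 and up to 3 labels
  for (T_ in 2:5) {
    rows <- as.matrix(expand.grid(rep(list(1:3), T_)))
    f <- temporal_flexibility(rows)
    oracle <- apply(rows, 1, bf_flexibility)
    expect_equal(unname(f), unname(oracle))
  }
  expect_error(temporal_flexibility(rbind(c(1))), "2 windows")
})

test_that("search information reproduces closed-form path and star values", {
  expect_equal(search_information(toys$path3$gamma, 1, 3), 1)
  expect_equal(search_information(toys$path3$gamma, 3, 1), 1)
  expect_equal(search_information(toys$star4$gamma, 2, 3), 2)
  S <- search_information(toys$star4$gamma)
  expect_true(all(diag(S) == 0))
})

test_that("search information agrees with the path-enumeration oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    gamma <- random_connected_gamma(n)
    S <- search_information(gamma)
    i <- sample(n, 1)
    j <- sample(setdiff(seq_len(n), i), 1)
    expect_lt(abs(S[i, j] - bf_search_info(gamma, i, j)), 1e-9)
  }
})

test_that("disconnected pairs are infinite and excluded from averages", {
  g <- matrix(0, 4, 4)
  g[1, 2] <- g[2, 1] <- 1
  g[3, 4] <- g[4, 3] <- 1
  diag(g) <- 1
  S <- search_information(g)
  expect_true(is.infinite(S[1, 3]))
  expect_equal(S[1, 2], 0) # sole neighbor: probability 1
  expect_message(cs <- channel_search_information(g), "disconnected")
  expect_true(all(is.finite(cs)))
})

test_that("module allegiance counts co-assignments exactly", {
  A <- rbind(
    a = c(1, 1, 1, 1, 1),
    b = c(1, 1, 1, 2, 2),
    c = c(2, 2, 2, 2, 2)
  )
  P <- module_allegiance(A)
  expect_equal(P["a", "b"], 0.6) # co-assigned 3 of 5 windows
  expect_equal(P["a", "a"], 1)
  expect_equal(P["a", "c"], 0)
  expect_equal(unclass(P), t(unclass(P)))

  always <- module_allegiance(rbind(c(1, 2, 1), c(1, 2, 1)))
  expect_true(all(always == 1))
})

test_that("allegiance of random partitions is symmetric with unit diagonal", {
  set.seed(17)
  for (rep in 1:100) {
    A <- matrix(sample(1:4, 6 * 8, replace = TRUE), 6, 8)
    P <- unclass(module_allegiance(A))
    expect_identical(P, t(P))
    expect_equal(diag(P), rep(1, 6))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("interaction strength follows the allegiance formula exactly", {
  # C1 = {a, b}, C2 = {c}; P_ac = 0.4, P_bc = 0.6 -> I_12 = 0.5
  P <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  P["a", "c"] <- P["c", "a"] <- 0.4
  P["b", "c"] <- P["c", "b"] <- 0.6
  ir <- integration_recruitment(P, list(C1 = 1:2, C2 = 3), normalize = FALSE)
  expect_equal(ir$integration[ir$region == "C1"], 0.5)

  ones <- matrix(1, 4, 4)
  ir2 <- integration_recruitment(ones, list(A = 1:2, B = 3:4))
  expect_equal(ir2$recruitment, c(1, 1))

  # regions never sharing a community: raw interaction 0
  A <- rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2))
  P3 <- module_allegiance(A)
  ir3 <- integration_recruitment(P3, list(A = 1:2, B = 3:4), normalize = FALSE)
  expect_equal(ir3$integration, c(0, 0))
  expect_equal(ir3$recruitment, c(1, 1))

  expect_error(integration_recruitment(ones, list(A = 1:4)), "two regions")
})

test_that("recruitment and raw interaction stay within [0, 1]", {
  set.seed(23)
  for (rep in 1:20) {
    A <- matrix(sample(1:3, 8 * 6, replace = TRUE), 8, 6)
    P <- module_allegiance(A)
    ir <- integration_recruitment(
      P, list(a = 1:3, b = 4:6, c = 7:8),
      normalize = FALSE
    )
    expect_true(all(ir$recruitment >= 0 & ir$recruitment <= 1))
    expect_true(all(ir$integration >= 0 & ir$integration <= 1))
  }
})

test_that("self-pair handling is exposed and behaves sensibly", {
  A <- rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
  P <- module_allegiance(A)
  with_self <- integration_recruitment(P, list(a = 1:2, b = 3:4))
  without <- integration_recruitment(P, list(a = 1:2, b = 3:4),
    include_self = FALSE
  )
  expect_gte(with_self$recruitment[1], without$recruitment[1])
})

test_that("consistent relabeling leaves all partition metrics unchanged", {
  set.seed(29)
  A <- matrix(sample(1:3, 10 * 6, replace = TRUE), 10, 6)
  A2 <- A
  for (t in seq_len(ncol(A))) {
    perm <- sample(3)
    A2[, t] <- perm[A[, t]]
  }
  expect_equal(module_allegiance(A2), module_allegiance(A))
  regions <- list(a = 1:4, b = 5:7, c = 8:10)
  expect_equal(
    integration_recruitment(module_allegiance(A2), regions),
    integration_recruitment(module_allegiance(A), regions)
  )
  # flexibility needs per-window-consistent relabeling, which this is not;
  # a global relabeling (same permutation every window) must preserve it
  perm <- sample(3)
  A3 <- matrix(perm[A], nrow(A))
  expect_equal(temporal_flexibility(A3), temporal_flexibility(A))
})

test_that("node strength matches a brute-force row-mean oracle", {
  m <- matrix(0.5, 3, 3)
  diag(m) <- 1
  expect_equal(unname(node_strength(m)), rep(0.5, 3))

  z <- matrix(0, 4, 4)
  expect_equal(unname(node_strength(z)), rep(0, 4))

  set.seed(37)
  g <- random_connected_gamma(6)
  s <- node_strength(g)
  oracle <- sapply(1:6, function(i) {
    tot <- 0
    for (j in setdiff(1:6, i)) tot <- tot + g[i, j]
    tot / 5
  })
  expect_equal(unname(s), oracle)
})

test_that("feature aggregation yields 84 per metric at BA level and 96 at cortex", {
  map <- load_ba_map()
  set.seed(41)
  rec <- new_recording(
    matrix(rnorm(116 * 1500), 116, 1500), 500, names(map$channel_ba),
    subject_id = "S1", trial_id = "T1", task = "MB2"
  )
  psd <- compute_psd(rec)
  fb <- band_power_features(psd, level = "ba")
  expect_equal(nrow(fb), 84) # one metric family, 21 BAs x 4 bands

  feats <- suppressMessages(extract_features(rec,
    level = "cortex",
    n_reps = 10, seed = 1
  ))
  expect_equal(nrow(feats), 96) # 6 metric families x 4 cortices x 4 bands
  expect_equal(length(unique(feats$feature)), 96)
  expect_equal(
    sort(unique(feats$metric)),
    sort(c(
      "strength", "search_information", "flexibility", "integration",
      "recruitment", "psd"
    ))
  )
})
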