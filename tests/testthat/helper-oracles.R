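# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, recursion, full enumeration) so they share no
# code path with the package implementations they check.

# change counter for one partition row
bf_flexibility <- function(row) {
  changes <- 0L
  for (t in seq_len(length(row) - 1L)) {
    if (row[t] != row[t + 1L]) changes <- changes + 1L
  }
  changes / (length(row) - 1L)
}

# all simple paths i -> j on the positive entries of gamma
bf_all_paths <- function(gamma, i, j) {
  n <- nrow(gamma)
  paths <- list()
  walk <- function(path) {
    tail <- path[length(path)]
    if (tail == j) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v != tail && !(v %in% path) && gamma[tail, v] > 0) {
        walk(c(path, v))
      }
    }
  }
  walk(i)
  paths
}

# search information by full path enumeration: find the shortest path(s)
# under lengths -log(w), average -log2 of the walker probability over ties
bf_search_info <- function(gamma, i, j, tol = 1e-9) {
  if (i == j) {
    return(0)
  }
  g <- gamma
  diag(g) <- 0
  s <- rowSums(g)
  paths <- bf_all_paths(g, i, j)
  if (!length(paths)) {
    return(Inf)
  }
  lens <- vapply(paths, function(p) {
    total <- 0
    for (k in seq_len(length(p) - 1L)) total <- total - log(g[p[k], p[k + 1L]])
    total
  }, 0)
  best <- which(lens <= min(lens) + tol)
  bits <- vapply(paths[best], function(p) {
    lp <- 0
    for (k in seq_len(length(p) - 1L)) {
      lp <- lp + log2(g[p[k], p[k + 1L]] / s[p[k]])
    }
    -lp
  }, 0)
  mean(bits)
}

# connectivity check on positive entries
bf_connected <- function(gamma) {
  g <- gamma
  diag(g) <- 0
  n <- nrow(g)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in seq_len(n)) {
        if (g[u, v] > 0 && !(v %in% seen)) {
          seen <- c(seen, v)
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  length(seen) == n
}

# random connected weighted graph with weights in (0, 1]
random_connected_gamma <- function(n, p_edge = 0.6) {
  repeat {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
      }
    }
    diag(w) <- 1
    if (bf_connected(w)) {
      return(w)
    }
  }
}

# pure-tone recording on a given channel set
sine_recording <- function(freq, rate = 500, duration_s = 4,
                           channels = c("C3", "C4"), amp = 1, phase = 0) {
  t <- seq_len(rate * duration_s) / rate
  x <- amp * sin(2 * pi * freq * t + phase)
  new_recording(
    matrix(rep(x, length(channels)), nrow = length(channels), byrow = TRUE),
    rate, channels
  )
}

# adjusted agreement between two labelings via best label matching
# (exact over permutations; community counts in tests are tiny)
label_agreement <- function(a, b) {
  la <- unique(a)
  lb <- unique(b)
  if (length(lb) > 7) {
    stop("label_agreement oracle only supports <= 7 communities")
  }
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  best <- 0
  for (p in perms(lb)) {
    mapped <- p[match(b, lb)]
    best <- max(best, mean(mapped == a))
  }
  best
}
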