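graph_from_gamma <- function(gamma) {
  if (is.null(dim(gamma)) || nrow(gamma) != ncol(gamma)) {
    abort("Adjacency matrix must be square.")
  }
  if (nrow(gamma) == 0L) abort("Empty graph.")
  if (any(gamma < 0)) abort("Adjacency weights must be nonnegative.")
  g <- gamma
  diag(g) <- 0
  igraph::graph_from_adjacency_matrix(g, mode = "undirected", weighted = TRUE)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Weighted Louvain community detection
#'
#' Greedy modularity maximization on a nonnegative symmetric weighted
#' adjacency matrix (resolution parameter `gamma`), seeded for
#' reproducibility. The returned partition's modularity is never below
#' that of the trivial one-community partition.
#'
#' @param gamma_mat symmetric nonnegative matrix; the diagonal is ignored.
#' @param resolution Louvain resolution parameter (1 = classic modularity).
#' @param seed integer seed; identical seeds give identical labels.
#' @return Integer community labels (1-based), one per node.
#' @export
louvain_partition <- function(gamma_mat, resolution = 1, seed = NULL) {
  g <- graph_from_gamma(gamma_mat)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(cl))
}

# Expected co-assignment probability of the label-permutation null for a
# set of partitions: for each partition, the chance two distinct nodes
# land in the same community when labels are shuffled across nodes.
null_coassignment <- function(parts) {
  n <- length(parts[[1]])
  if (n < 2L) {
    return(0)
  }
  mean(vapply(parts, function(p) {
    sz <- tabulate(p)
    sum(sz * (sz - 1)) / (n * (n - 1))
  }, 0))
}

coassignment_matrix <- function(parts) {
  n <- length(parts[[1]])
  acc <- matrix(0, n, n)
  for (p in parts) acc <- acc + outer(p, p, "==")
  acc / length(parts)
}

#' Consensus community partition
#'
#' Runs seeded Louvain `n_reps` times, forms the node co-assignment
#' matrix, zeroes entries at or below the mean co-assignment expected
#' under a label-permutation (Newman-Girvan-style) null, re-clusters the
#' thresholded matrix, and iterates until the co-assignment matrix is
#' block-binary (all entries 0 or 1) or `max_iter` is reached, in which
#' case the current partition is returned with a warning.
#'
#' @inheritParams louvain_partition
#' @param n_reps Louvain repetitions per iteration (100 by default).
#' @param seed master seed; the per-repetition seeds are derived from it.
#' @param max_iter consensus iteration cap.
#' @return Integer community labels.
#' @export
consensus_partition <- function(gamma_mat, n_reps = 100, resolution = 1,
                                seed = 1, max_iter = 50) {
  graph_from_gamma(gamma_mat) # validate input up front
  cur <- gamma_mat
  diag(cur) <- 0
  for (it in seq_len(max_iter)) {
    parts <- lapply(seq_len(n_reps), function(r) {
      louvain_partition(cur, resolution = resolution, seed = seed + (it - 1) * n_reps + r)
    })
    D <- coassignment_matrix(parts)
    if (all(D %in% c(0, 1))) {
      return(as.integer(factor(apply(D, 1, paste, collapse = ""))))
    }
    tau <- null_coassignment(parts)
    D[D <= tau] <- 0
    diag(D) <- 0
    cur <- D
  }
  warn("Consensus clustering did not converge; returning the current partition.")
  louvain_partition(cur, resolution = resolution, seed = seed)
}

# Relabel `cur` so its labels line up with `prev` by maximum-overlap
# assignment on the label contingency table (solved as a maximum-weight
# bipartite matching); labels with no match get fresh integers.
align_to_previous <- function(prev, cur) {
  pl <- sort(unique(prev))
  cl <- sort(unique(cur))
  tab <- table(factor(prev, pl), factor(cur, cl))
  np <- length(pl)
  nc <- length(cl)
  el <- which(tab > 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nc)),
    edges = as.vector(t(cbind(el[, 1], np + el[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = tab[el])$matching
  newlab <- integer(nc)
  next_free <- max(pl) + 1L
  for (j in seq_len(nc)) {
    partner <- m[np + j]
    if (!is.na(partner)) {
      newlab[j] <- pl[partner]
    } else {
      newlab[j] <- next_free
      next_free <- next_free + 1L
    }
  }
  newlab[match(cur, cl)]
}

#' Partition matrix across time windows
#'
#' Runs [consensus_partition()] on every window of a coherence stack and
#' aligns community labels between consecutive windows by maximum-overlap
#' matching, so that a label change in the resulting matrix reflects a
#' genuine change of community membership rather than arbitrary label
#' numbering.
#'
#' @param stack a [windowed_networks()] coherence stack (>= 2 windows).
#' @inheritParams consensus_partition
#' @return A `partition_matrix`: list with `A` (channels x windows integer
#'   matrix), `channels`, `band`, `window_index`.
#' @export
build_partition_matrix <- function(stack, n_reps = 100, resolution = 1,
                                   seed = 1, max_iter = 50) {
  T_ <- length(stack$windows)
  if (T_ < 2L) abort("A partition matrix needs at least 2 windows.")
  cols <- vector("list", T_)
  for (t in seq_len(T_)) {
    cols[[t]] <- consensus_partition(
      stack$windows[[t]],
      n_reps = n_reps, resolution = resolution,
      seed = seed + (t - 1L) * n_reps * max_iter, max_iter = max_iter
    )
    if (t > 1L) cols[[t]] <- align_to_previous(cols[[t - 1L]], cols[[t]])
  }
  A <- do.call(cbind, cols)
  rownames(A) <- stack$channels
  structure(
    list(
      A = A, channels = stack$channels, band = stack$band,
      window_index = stack$window_index,
      subject_id = stack$subject_id, trial_id = stack$trial_id,
      task = stack$task
    ),
    class = "partition_matrix"
  )
}

#' @export
print.partition_matrix <- function(x, ...) {
  cat(sprintf(
    "<partition_matrix> %d channels x %d windows, %d communities (band %s)\n",
    nrow(x$A), ncol(x$A), length(unique(as.vector(x$A))), x$band
  ))
  invisible(x)
}
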