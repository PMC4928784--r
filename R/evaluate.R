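#' Parameter-recovery statistic W
#'
#' A chi-squared-style discrepancy between predicted and actual event-type
#' frequencies: `W = sum_i (P_i - A_i)^2 / A_i`. Small values mean accurate
#' rate recovery; `W = 0` iff the distributions coincide.
#'
#' @param predicted,actual Named frequency vectors over the same event types.
#' @return Nonnegative numeric scalar.
#' @export
w_statistic <- function(predicted, actual) {
  keys <- union(names(predicted), names(actual))
  p <- stats::setNames(rep(0, length(keys)), keys)
  a <- p
  p[names(predicted)] <- predicted
  a[names(actual)] <- actual
  if (any(a == 0)) {
    stop("actual frequency is zero for event type(s): ",
         paste(keys[a == 0], collapse = ", "))
  }
  sum((p - a)^2 / a)
}

# multiset of edge-deletion bipartitions, canonicalized on the shared
# pattern set: key = sorted members of the side away from the root
bipartition_keys <- function(tree, shared) {
  n <- nrow(tree$states)
  if (n < 2L) return(character(0))
  keys <- rownames(tree$states)
  children <- split(seq_len(n)[-1L], tree$parent[-1L])
  below <- vector("list", n)
  ord <- order(tree_depths(tree), decreasing = TRUE)
  for (v in ord) {
    kids <- children[[as.character(v)]]
    below[[v]] <- c(keys[v], unlist(below[kids]))
  }
  # bracketed so the empty restricted side still yields an indexable key
  vapply(seq_len(n)[-1L], function(v) {
    paste0("[", paste(sort(intersect(below[[v]], shared)), collapse = "|"), "]")
  }, "")
}

#' Bipartition reconstruction error between two trees
#'
#' Compares tree topologies through the node-set bipartitions induced by
#' deleting each edge, restricted to the patterns the two trees share.
#' `M` is the total weight of a maximum-weight bipartite matching between
#' the two bipartition multisets, where the weight of pairing two
#' bipartitions is the Jaccard similarity of their root-distal sides
#' (1 iff they split the shared node set identically); the error is
#' `R = (1 - M / (|Ps| + |Pg| - M)) * 100`, from 0 (identical trees) to 100
#' (nothing matchable). Nodes absent from either tree (e.g. Steiner
#' mismatches) are ignored by the restriction.
#'
#' @param simulated,generated `"progression_tree"` objects on one panel.
#' @return Error percentage in `[0, 100]`.
#' @export
reconstruction_error <- function(simulated, generated) {
  stopifnot(inherits(simulated, "progression_tree"),
            inherits(generated, "progression_tree"))
  shared <- intersect(rownames(simulated$states), rownames(generated$states))
  ps <- bipartition_sets(simulated, shared)
  pg <- bipartition_sets(generated, shared)
  if (length(ps) + length(pg) == 0L) return(0)
  if (length(ps) == 0L || length(pg) == 0L) return(100)
  # two splits whose restricted sides are both empty carry no information
  # about the shared nodes and are not matchable
  w <- matrix(0, length(ps), length(pg))
  for (i in seq_along(ps)) {
    for (j in seq_along(pg)) {
      u <- length(union(ps[[i]], pg[[j]]))
      w[i, j] <- if (u == 0L) 0 else
        length(intersect(ps[[i]], pg[[j]])) / u
    }
  }
  m <- max_weight_assignment(w)
  (1 - m / (length(ps) + length(pg) - m)) * 100
}

# root-distal side of each edge-deletion split, restricted to the shared
# pattern set (list of character vectors, one per edge)
bipartition_sets <- function(tree, shared) {
  n <- nrow(tree$states)
  if (n < 2L) return(list())
  keys <- rownames(tree$states)
  children <- split(seq_len(n)[-1L], tree$parent[-1L])
  below <- vector("list", n)
  ord <- order(tree_depths(tree), decreasing = TRUE)
  for (v in ord) {
    kids <- children[[as.character(v)]]
    below[[v]] <- c(keys[v], unlist(below[kids]))
  }
  lapply(seq_len(n)[-1L], function(v) intersect(below[[v]], shared))
}

# exact maximum-weight assignment (rectangular, weights >= 0): pad to a
# square cost matrix and run the O(n^3) potentials-based Hungarian
# algorithm; returns the total weight of the optimal assignment
max_weight_assignment <- function(w) {
  n <- max(dim(w))
  mx <- max(w)
  cost <- matrix(mx, n, n)
  cost[seq_len(nrow(w)), seq_len(ncol(w))] <- mx - w
  # columns indexed 0..n are stored at offset +1; p[j+1] = row matched to j
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  total <- 0
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i <= nrow(w) && j <= ncol(w)) total <- total + w[i, j]
  }
  total
}

#' Total and average tree weight
#'
#' The weight of a tree is the sum over edges of `-log p`, where each edge's
#' probability multiplies the frequencies of its (decomposed) event types.
#' It is interpretable as a negative log-likelihood of the tree; the average
#' weight per edge estimates the Shannon entropy of the event-type
#' distribution when edges are elementary.
#'
#' @param tree A `"progression_tree"`.
#' @param freqs Event frequencies; default: the tree's attached frequencies,
#'   or the distribution tallied from its own edges.
#' @return `tree_weight()`: nonnegative scalar; `avg_edge_weight()`: weight
#'   per edge (tree must have at least one edge).
#' @export
tree_weight <- function(tree, freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- if (!is.null(tree$freqs)) tree$freqs else tree_event_frequencies(tree)
  }
  total <- 0
  for (v in seq_len(nrow(tree$states))[-1L]) {
    dec <- decompose_edge(tree$states[tree$parent[v], ], tree$states[v, ])
    if (is.null(dec)) next
    w <- sum(vapply(dec, event_weight, 0, freqs = freqs))
    if (!is.finite(w)) stop("edge with zero-probability event")
    total <- total + w
  }
  total
}

#' @rdname tree_weight
#' @export
avg_edge_weight <- function(tree, freqs = NULL) {
  if (n_edges(tree) < 1L) stop("tree has no edges")
  tree_weight(tree, freqs) / n_edges(tree)
}

#' Expected depth of an observed cell
#'
#' Sum over nodes of depth times the fraction of observed cells assigned to
#' that node; the all-2 root has depth zero. Deeper expected depth indicates
#' a more progressed sample.
#'
#' @param tree A `"progression_tree"`.
#' @param ds Optional [fish_data()]; every observed pattern must be a node
#'   of the tree. Default: the cell counts stored on the tree.
#' @return Nonnegative numeric scalar.
#' @export
expected_depth <- function(tree, ds = NULL) {
  depth <- tree_depths(tree)
  if (is.null(ds)) {
    counts <- tree$ncells
  } else {
    keys <- aligned_pattern_keys(ds, tree$panel)
    idx <- match(keys, rownames(tree$states))
    if (any(is.na(idx))) {
      stop("observed pattern(s) missing from the tree: ",
           paste(keys[is.na(idx)], collapse = "; "))
    }
    counts <- numeric(nrow(tree$states))
    counts[idx] <- ds$counts
  }
  tot <- sum(counts)
  if (tot == 0) return(0)
  sum(depth * counts) / tot
}

#' Shannon entropy and Simpson index of a frequency distribution
#'
#' Complexity measures of the inferred event-type parameters: entropy
#' `-sum p log p` (natural log; larger = closer to uniform) and Simpson
#' index `sum p^2` (smaller = closer to uniform).
#'
#' @param freqs Frequency vector (nonnegative, summing to 1).
#' @return Numeric scalar.
#' @export
shannon_entropy <- function(freqs) {
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' @rdname shannon_entropy
#' @export
simpson_index <- function(freqs) {
  sum(freqs^2)
}

#' Coverage of observed states and Steiner fraction of a tree
#'
#' `coverage()` is the fraction of the dataset's distinct observed patterns
#' present as nodes of the tree; `steiner_fraction()` is the fraction of
#' tree nodes that are unobserved (Steiner) states.
#'
#' @param tree A `"progression_tree"`.
#' @param ds A [fish_data()] on the same panel.
#' @return Numeric scalar in `[0, 1]`.
#' @export
coverage <- function(tree, ds) {
  stopifnot(inherits(ds, "fish_data"))
  mean(aligned_pattern_keys(ds, tree$panel) %in% rownames(tree$states))
}

# dataset pattern keys with columns reordered to the panel's probe order
aligned_pattern_keys <- function(ds, panel) {
  want <- probe_names(panel)
  have <- colnames(ds$patterns)
  if (!setequal(want, have)) {
    stop("dataset probes (", paste(have, collapse = ", "),
         ") do not match the tree panel (", paste(want, collapse = ", "), ")")
  }
  pattern_key(ds$patterns[, want, drop = FALSE])
}

#' @rdname coverage
#' @export
steiner_fraction <- function(tree) {
  mean(tree$steiner)
}

#' Bootstrap retention of distinct states
#'
#' Estimates how many of a sample's distinct cell-count patterns would recur
#' if the same number of cells were re-drawn from the empirical pattern
#' distribution: replicates are sampled with replacement at the original
#' sample size, and the mean fraction of distinct observed patterns retained
#' per replicate is returned. Low retention indicates that a sizeable share
#' of unobserved (Steiner) states is expected at this sample size.
#'
#' @param ds A [fish_data()] object.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @return Mean retention fraction in `(0, 1]`.
#' @export
state_retention_bootstrap <- function(ds, n_reps = 100L) {
  stopifnot(inherits(ds, "fish_data"))
  m <- nrow(ds$patterns)
  ncells <- total_cells(ds)
  prob <- ds$counts / ncells
  mean(vapply(seq_len(n_reps), function(i) {
    draw <- stats::rmultinom(1L, ncells, prob)
    sum(draw > 0) / m
  }, 0))
}
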