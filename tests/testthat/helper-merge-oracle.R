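# Independent oracle for the tree-merging program: exhaustive enumeration of
# feasible integer assignments (labels per node pair: none / a / b / c), with
# the inner continuous subproblem (minimize sigma * sum |p - q| subject to
# the marginal equalities and q supported on selected pairs) solved by
# boot::simplex. Shares nothing with the HiGHS backend.

# minimal L1 frequency-mismatch cost for a selection matrix; NULL if the
# marginal constraints are infeasible on this support
oracle_inner_l1 <- function(p, sel) {
  # tiny jitter on carried entries breaks vertex degeneracy, which the
  # boot::simplex pivoting cannot handle; it moves the optimum by < 1e-7,
  # far inside the comparison tolerance
  jit <- which(sel == 1 | p > 0)
  p[jit] <- p[jit] + stats::runif(length(jit), 1e-9, 1e-8)
  rp <- rowSums(p); cp <- colSums(p)
  # q is forced to zero on pairs whose row or column marginal is zero, so
  # only pairs with positive marginals on both sides are free variables
  # (dropping the forced zeros avoids degenerate zero equalities in the LP)
  free <- sel == 1 & rp[row(p)] > 0 & cp[col(p)] > 0
  if (any(rp > 0 & rowSums(free) == 0) || any(cp > 0 & colSums(free) == 0)) {
    return(NULL)  # a positive marginal cannot be carried: infeasible support
  }
  idx <- which(free)
  if (length(idx) == 0L) return(sum(p))
  k <- length(idx)
  ri <- row(p)[idx]; ci <- col(p)[idx]; pv <- p[idx]
  # variables x = (q_1..q_k, t_1..t_k), minimize sum t
  obj <- c(rep(0, k), rep(1, k))
  # q - t <= p (q <= 1 is implied by the row-marginal equalities)
  A1 <- cbind(diag(k), -diag(k))
  b1 <- pv
  # q + t >= p
  A2 <- cbind(diag(k), diag(k))
  b2 <- pv
  # row and column marginal equalities; the system is rank-deficient (row
  # sums and column sums both add to one), so keep a full-rank subset and
  # verify the dropped equalities on the solution afterwards
  m <- nrow(p); n <- ncol(p)
  A3r <- matrix(0, m, 2 * k); A3c <- matrix(0, n, 2 * k)
  for (e in seq_len(k)) {
    A3r[ri[e], e] <- 1
    A3c[ci[e], e] <- 1
  }
  A3full <- rbind(A3r[rp > 0, , drop = FALSE], A3c[cp > 0, , drop = FALSE])
  b3full <- c(rp[rp > 0], cp[cp > 0])
  dec <- qr(t(A3full))
  keep <- dec$pivot[seq_len(dec$rank)]
  A3 <- A3full[keep, , drop = FALSE]
  b3 <- b3full[keep]
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = FALSE, n.iter = 500 + 50 * k),
    error = function(e) NULL)
  if (is.null(res)) stop("oracle inner LP failed; degenerate instance")
  if (res$solved != 1) return(NULL)
  if (max(abs(A3full %*% res$soln - b3full)) > 1e-7) {
    return(NULL)  # dropped equalities inconsistent: support infeasible
  }
  # pairs outside the free set are forced to q = 0 and contribute |p - 0|
  unname(res$value) + sum(p[-idx])
}

# exhaustive minimum objective over all feasible assignments
merge_oracle <- function(pr) {
  m <- pr$m; n <- pr$n
  pairs <- expand.grid(i = seq_len(m), j = seq_len(n))
  np <- nrow(pairs)
  choices <- lapply(seq_len(np), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (i == 1L && j == 1L) 3L          # c_11 = 1
    else if (i == 1L) c(0L, 2L)         # row 1: only b
    else if (j == 1L) c(0L, 1L)         # column 1: only a
    else 0:3
  })
  grid <- as.matrix(expand.grid(choices))
  best <- Inf
  inner_cache <- new.env(parent = emptyenv())
  for (g in seq_len(nrow(grid))) {
    lab <- matrix(0L, m, n)
    lab[cbind(pairs$i, pairs$j)] <- grid[g, ]
    sel <- (lab > 0L) * 1L
    ok <- TRUE
    for (r in seq_len(np)) {
      i <- pairs$i[r]; j <- pairs$j[r]
      L <- lab[i, j]
      if (L == 0L || (i == 1L && j == 1L)) next
      k <- pr$parentA[i]; l <- pr$parentB[j]
      need <- switch(L, sel[k, j], sel[i, l], sel[k, l])
      if (need != 1L) { ok <- FALSE; break }
    }
    if (!ok) next
    # all edges of trees A and B used
    if (m > 1L && any(rowSums(lab == 1L | lab == 3L)[-1L] == 0)) next
    if (n > 1L && any(colSums(lab == 2L | lab == 3L)[-1L] == 0)) next
    key <- paste(sel, collapse = "")
    if (is.null(inner_cache[[key]])) {
      v <- oracle_inner_l1(pr$p, sel)
      inner_cache[[key]] <- if (is.null(v)) NA_real_ else v
    }
    f3 <- inner_cache[[key]]
    if (is.na(f3)) next
    f1 <- sum(pr$wA[pairs$i][grid[g, ] == 1L]) +
      sum(pr$wB[pairs$j][grid[g, ] == 2L]) +
      sum((pr$wA[pairs$i] + pr$wB[pairs$j])[grid[g, ] == 3L])
    f2 <- pr$rho * sum(sel * pr$mismatch)
    f4 <- pr$tau * sum((1 - sel)[pr$p > 0])
    total <- f1 + f2 + pr$sigma * f3 + f4
    if (total < best) best <- total
  }
  unname(best)
}

# random small merge problem (m, n <= 3) with integer-grid frequencies
random_merge_problem <- function(max_nodes = 3L) {
  pan <- toy_panel()
  panA <- probe_panel("cep", "gA")
  panB <- probe_panel("cep", "gB")
  rand_tree <- function(panel) {
    n <- sample(seq_len(max_nodes), 1L)
    tree <- simulate_tree(uniform_frequencies(1L), n, panel)
    draw <- stats::rgamma(6, 1)
    tree$freqs <- ploidytree:::apply_floor(
      stats::setNames(draw / sum(draw), rownames(event_types(1L))))
    tree
  }
  ta <- rand_tree(panA); tb <- rand_tree(panB)
  # joint observations pair nodes with matching ploidy so both marginals
  # exist in their trees (as they do for real per-cell data)
  k <- sample(1:4, 1L)
  pats <- matrix(integer(0), 0L, 3L)
  counts <- integer(0)
  for (d in seq_len(k)) {
    i <- sample(nrow(ta$states), 1L)
    cand <- which(tb$states[, 1L] == ta$states[i, 1L])
    if (length(cand) == 0L) { i <- 1L; cand <- 1L }
    j <- cand[sample(length(cand), 1L)]
    pats <- rbind(pats, c(ta$states[i, ], tb$states[j, 2L]))
    counts <- c(counts, sample(1:20, 1L))
  }
  keep <- !duplicated(pats)
  ds <- fish_data(pats[keep, , drop = FALSE], counts[keep], pan)
  build_merge_problem(ta, tb, ds, rho = 1000, sigma = 100, tau = 100)
}
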