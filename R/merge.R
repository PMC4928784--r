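#' Build a tree-merging problem instance
#'
#' Prepares the mixed-integer linear program that merges two progression
#' trees over disjoint gene-probe sets (sharing the ploidy probe) into one
#' tree over the union probe set. Tree nodes are indexed with the root at
#' index 1; `p[i, j]` is the observed frequency of the joint state pairing
#' node `i` of tree A with node `j` of tree B (zero when never observed),
#' normalized over all pairs; `wA`/`wB` are the `-log p` weights of the edge
#' into each node under each tree's event frequencies (root weight 0).
#'
#' @param treeA,treeB `"progression_tree"` objects with event frequencies
#'   attached, rooted at the all-2 state, over disjoint gene sets.
#' @param joint_ds A [fish_data()] whose panel contains both trees' probes.
#' @param rho,sigma,tau Penalties: ploidy mismatch, node-frequency mismatch,
#'   missing observed data (defaults 1000, 100, 100).
#' @return An object of class `"merge_problem"`.
#' @export
build_merge_problem <- function(treeA, treeB, joint_ds,
                                rho = 1000, sigma = 100, tau = 100) {
  stopifnot(inherits(treeA, "progression_tree"),
            inherits(treeB, "progression_tree"),
            inherits(joint_ds, "fish_data"))
  pa <- treeA$panel; pb <- treeB$panel
  if (!identical(pa$ploidy, pb$ploidy) || pa$max_copy != pb$max_copy) {
    stop("trees must share the ploidy probe and max_copy")
  }
  if (length(intersect(pa$genes, pb$genes)) > 0L) {
    stop("gene probe sets must be disjoint")
  }
  if (is.null(treeA$freqs) || is.null(treeB$freqs)) {
    stop("both trees need event frequencies to derive edge weights")
  }
  joint_panel <- probe_panel(pa$ploidy, c(pa$genes, pb$genes), pa$max_copy)
  dsj <- marginalize(joint_ds, probe_names(joint_panel))

  m <- nrow(treeA$states); n <- nrow(treeB$states)
  # locate each joint pattern's marginals in the two trees; index columns by
  # probe name (marginalize keeps the original panel's column order)
  keyA <- pattern_key(dsj$patterns[, c(pa$ploidy, pa$genes), drop = FALSE])
  keyB <- pattern_key(dsj$patterns[, c(pb$ploidy, pb$genes), drop = FALSE])
  ia <- match(keyA, rownames(treeA$states))
  ib <- match(keyB, rownames(treeB$states))
  if (any(is.na(ia)) || any(is.na(ib))) {
    miss <- unique(c(keyA[is.na(ia)], keyB[is.na(ib)]))
    stop("joint pattern marginal(s) absent from an input tree: ",
         paste(miss, collapse = "; "))
  }
  total <- total_cells(dsj)
  p <- matrix(0, m, n)
  for (r in seq_along(ia)) {
    p[ia[r], ib[r]] <- p[ia[r], ib[r]] + dsj$counts[r] / total
  }
  mismatch <- outer(treeA$states[, 1L], treeB$states[, 1L], `!=`)

  edge_into_weight <- function(tree) {
    w <- numeric(nrow(tree$states))
    for (v in seq_len(nrow(tree$states))[-1L]) {
      dec <- decompose_edge(tree$states[tree$parent[v], ], tree$states[v, ])
      w[v] <- sum(vapply(dec, event_weight, 0, freqs = tree$freqs))
    }
    w
  }

  structure(
    list(m = m, n = n,
         treeA = treeA, treeB = treeB,
         parentA = treeA$parent, parentB = treeB$parent,
         wA = edge_into_weight(treeA), wB = edge_into_weight(treeB),
         p = p, mismatch = mismatch, total_cells = total,
         rho = rho, sigma = sigma, tau = tau,
         panel = joint_panel),
    class = "merge_problem"
  )
}

#' @export
print.merge_problem <- function(x, ...) {
  cat("Tree merge problem: ", x$m, " x ", x$n, " node pairs, ",
      sum(x$p > 0), " observed joint state(s), penalties rho=", x$rho,
      " sigma=", x$sigma, " tau=", x$tau, "\n", sep = "")
  invisible(x)
}

#' Solve a tree-merging problem
#'
#' Solves the merge MILP exactly (branch and bound, zero optimality gap) and
#' reconstructs the merged progression tree from the selected edge variables:
#' pair `(i, j)` is a node of the merged tree iff `a + b + c = 1` there; an
#' `a` edge descends from `(parentA(i), j)`, a `b` edge from
#' `(i, parentB(j))`, and a `c` edge from `(parentA(i), parentB(j))`. Pairs
#' never observed jointly (`p = 0`) become Steiner nodes. Every solution is
#' verified against all program constraints and the tree property before it
#' is returned.
#'
#' @param problem A `"merge_problem"`.
#' @param control A [ploidytree_control()].
#' @return A list with components `solution` (class `"merge_solution"`:
#'   binary matrices `a`, `b`, `c`, frequency matrix `q`, `objective`,
#'   `status`) and `tree` (the merged `"progression_tree"`).
#' @export
solve_merge <- function(problem, control = ploidytree_control()) {
  solve_merge_batch(list(problem), control)[[1L]]
}

#' Solve many merge problems in one backend invocation
#'
#' @param problems List of `"merge_problem"` objects.
#' @param control A [ploidytree_control()].
#' @return List of results as in [solve_merge()], one per problem.
#' @export
solve_merge_batch <- function(problems, control = ploidytree_control()) {
  stopifnot(all(vapply(problems, inherits, TRUE, "merge_problem")))
  raw <- milp_solve_batch(problems, control)
  Map(function(pr, s) {
    sol <- structure(
      list(a = backend_matrix(s$a, pr$m, pr$n),
           b = backend_matrix(s$b, pr$m, pr$n),
           c = backend_matrix(s$c, pr$m, pr$n),
           q = backend_matrix(s$q, pr$m, pr$n),
           objective = s$objective, status = s$status),
      class = "merge_solution")
    check_merge_solution(sol, pr)
    list(solution = sol, tree = merged_tree_from_solution(sol, pr))
  }, problems, raw)
}

# verify every printed constraint and the tree property on the solution
check_merge_solution <- function(sol, pr, tol = 1e-6) {
  a <- sol$a; b <- sol$b; c <- sol$c; q <- sol$q
  stopifnot(all(a %in% 0:1), all(b %in% 0:1), all(c %in% 0:1))
  sel <- a + b + c
  fail <- function(msg) stop("merge solution violates a constraint: ", msg)
  if (any(sel > 1 + tol)) fail("node with more than one parent")
  if (c[1L, 1L] != 1 || a[1L, 1L] != 0 || b[1L, 1L] != 0) fail("root rule c11=1")
  if (any(a[1L, ] != 0) || any(c[1L, -1L] != 0)) fail("fixed variables, row 1")
  if (any(b[, 1L] != 0) || any(c[-1L, 1L] != 0)) fail("fixed variables, column 1")
  if (any(q < -tol) || any(q > sel + tol)) fail("q outside [0, a+b+c]")
  for (i in seq_len(pr$m)[-1L]) {
    k <- pr$parentA[i]
    if (any(a[i, ] > sel[k, ] + tol)) fail("a edge without selected parent")
  }
  for (j in seq_len(pr$n)[-1L]) {
    l <- pr$parentB[j]
    if (any(b[, j] > sel[, l] + tol)) fail("b edge without selected parent")
  }
  for (i in seq_len(pr$m)[-1L]) {
    k <- pr$parentA[i]
    for (j in seq_len(pr$n)[-1L]) {
      l <- pr$parentB[j]
      if (c[i, j] > sel[k, l] + tol) fail("c edge without selected parent")
    }
  }
  if (max(abs(rowSums(q) - rowSums(pr$p))) > tol) fail("row marginals")
  if (max(abs(colSums(q) - colSums(pr$p))) > tol) fail("column marginals")
  if (pr$m > 1L && any(rowSums(a + c)[-1L] < 1 - tol)) fail("unused tree-A edge")
  if (pr$n > 1L && any(colSums(b + c)[-1L] < 1 - tol)) fail("unused tree-B edge")
  # tree property: selected pairs form a tree rooted at (1,1)
  pairs <- which(sel >= 1 - tol, arr.ind = TRUE)
  key <- paste(pairs[, 1L], pairs[, 2L])
  parent_pair <- function(i, j) {
    if (a[i, j] == 1) c(pr$parentA[i], j)
    else if (b[i, j] == 1) c(i, pr$parentB[j])
    else c(pr$parentA[i], pr$parentB[j])
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (i == 1L && j == 1L) next
    pp <- parent_pair(i, j)
    if (!(paste(pp[1L], pp[2L]) %in% key)) fail("selected node with unselected parent")
  }
  invisible(TRUE)
}

# objective recomputed in R from a solution (used by tests and the oracle)
merge_objective <- function(sol, pr) {
  sel <- sol$a + sol$b + sol$c
  f1 <- sum(sol$a * pr$wA) + sum(t(sol$b) * pr$wB) +
    sum(sol$c * pr$wA) + sum(t(sol$c) * pr$wB)
  f2 <- pr$rho * sum(sel * pr$mismatch)
  f3 <- pr$sigma * sum(abs(pr$p - sol$q))
  f4 <- pr$tau * sum((1 - sel)[pr$p > 0])
  f1 + f2 + f3 + f4
}

# build the merged progression tree: joint state takes its ploidy from the
# tree-A node (ploidy-mismatched pairs always have p = 0 and pay rho)
merged_tree_from_solution <- function(sol, pr) {
  sel <- sol$a + sol$b + sol$c
  pairs <- which(sel >= 1, arr.ind = TRUE)
  ord <- order(pairs[, 1L] != 1L | pairs[, 2L] != 1L,
               pairs[, 1L], pairs[, 2L])  # root pair first
  pairs <- pairs[ord, , drop = FALSE]
  key <- paste(pairs[, 1L], pairs[, 2L])
  states <- t(apply(pairs, 1L, function(ij) {
    c(pr$treeA$states[ij[1L], ], pr$treeB$states[ij[2L], -1L])
  }))
  parent <- rep(NA_integer_, nrow(pairs))
  ew <- rep(NA_real_, nrow(pairs))   # -log p of the edge into each pair (f1)
  for (r in seq_len(nrow(pairs))[-1L]) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (sol$a[i, j] == 1) {
      pp <- c(pr$parentA[i], j); ew[r] <- pr$wA[i]
    } else if (sol$b[i, j] == 1) {
      pp <- c(i, pr$parentB[j]); ew[r] <- pr$wB[j]
    } else {
      pp <- c(pr$parentA[i], pr$parentB[j]); ew[r] <- pr$wA[i] + pr$wB[j]
    }
    parent[r] <- match(paste(pp[1L], pp[2L]), key)
  }
  pobs <- pr$p[pairs]
  steiner <- pobs == 0
  ncells <- pobs * pr$total_cells
  # Distinct pairs can map to one joint pattern when a ploidy-mismatched
  # Steiner pair shadows a matched one (the joint state takes tree A's
  # ploidy). Contract such duplicates onto the representative nearest the
  # root (observed first): ancestors have strictly smaller depth, so
  # re-pointing children onto the kept node cannot create a cycle.
  nn <- nrow(states)
  depth <- rep(NA_real_, nn)
  depth[1L] <- 0
  for (r in seq_len(nn)) {
    chain <- integer(0)
    v <- r
    while (is.na(depth[v])) {
      chain <- c(chain, v)
      v <- parent[v]
    }
    if (length(chain) > 0L) depth[chain] <- depth[v] + seq(length(chain), 1L)
  }
  skey <- pattern_key(states)
  drop <- logical(nn)
  for (grp in split(seq_len(nn), skey)) {
    if (length(grp) < 2L) next
    keep <- grp[order(depth[grp], steiner[grp], grp)][1L]
    del <- setdiff(grp, keep)
    parent[parent %in% del] <- keep
    ncells[keep] <- sum(ncells[grp])
    steiner[keep] <- all(steiner[grp])
    drop[del] <- TRUE
  }
  if (any(drop)) {
    remap <- cumsum(!drop)
    states <- states[!drop, , drop = FALSE]
    parent <- remap[parent[!drop]]
    parent[1L] <- NA_integer_
    steiner <- steiner[!drop]
    ncells <- ncells[!drop]
    ew <- ew[!drop]
  }
  tree <- progression_tree(states, parent, steiner = steiner,
                           ncells = ncells, panel = pr$panel)
  tree$freqs <- tree_event_frequencies(tree)
  tree$edge_weight <- ew
  tree
}

#' Merge a list of single-gene trees into one multi-probe tree
#'
#' Sequential left fold of [solve_merge()] in the given order: the first two
#' trees are merged, the intermediate tree is re-weighted from the decomposed
#' event tallies of its own edges, then the next tree is merged in, and so
#' on. The outcome can depend on the merge order, which is recorded on the
#' result.
#'
#' @param trees List of `>= 2` progression trees over disjoint gene-probe
#'   sets sharing the ploidy probe.
#' @param joint_ds A [fish_data()] covering all probes involved.
#' @param control A [ploidytree_control()] (penalties and solver settings).
#' @return The merged `"progression_tree"`, with attribute `"merge_order"`.
#' @export
merge_all <- function(trees, joint_ds, control = ploidytree_control()) {
  stopifnot(length(trees) >= 2L)
  genes <- lapply(trees, function(t) t$panel$genes)
  if (length(unlist(genes)) != length(unique(unlist(genes)))) {
    stop("gene probe sets of the input trees must be disjoint")
  }
  acc <- trees[[1L]]
  for (k in seq_along(trees)[-1L]) {
    pr <- build_merge_problem(acc, trees[[k]], joint_ds,
                              rho = control$rho, sigma = control$sigma,
                              tau = control$tau)
    acc <- solve_merge(pr, control)$tree
  }
  attr(acc, "merge_order") <- vapply(trees, function(t)
    paste(t$panel$genes, collapse = "+"), "")
  acc
}

#' Event-type frequencies tallied from a tree's edges
#'
#' Decomposes every edge of the tree into allowed events with
#' [decompose_edge()] and returns the floored, normalized distribution of
#' event types. This is the distribution "inferred from the tree" used for
#' edge weights, entropy, and parameter-recovery statistics. Edges whose
#' ploidy changes by 2 or more are ignored.
#'
#' @param tree A `"progression_tree"`.
#' @param floor Probability floor.
#' @return Named frequency vector over the allowed event types.
#' @export
tree_event_frequencies <- function(tree, floor = 1e-6) {
  tally <- tree_event_tally(tree)
  normalize_tally(tally, n_genes(tree$panel), floor)
}

# raw decomposed event counts of a tree's edges (named integer-ish vector)
tree_event_tally <- function(tree) {
  tally <- numeric(0)
  for (v in seq_len(nrow(tree$states))[-1L]) {
    dec <- decompose_edge(tree$states[tree$parent[v], ], tree$states[v, ])
    if (is.null(dec)) next
    for (d in dec) {
      key <- paste(d, collapse = ",")
      tally[key] <- (if (is.na(tally[key])) 0 else tally[key]) + 1
    }
  }
  tally
}
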