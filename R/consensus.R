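#' Build a consensus graph from trees over the same probe panel
#'
#' The consensus graph contains every node (cell-count state) and every edge
#' that appears in at least one of the input trees, annotated with the set of
#' trees each belongs to. It summarizes what paired (or repeated) samples of
#' one patient share and where they diverge.
#'
#' @param trees List of `>= 2` `"progression_tree"` objects on identical
#'   probe panels with the common all-2 root.
#' @return An object of class `"consensus_graph"`: node table (pattern,
#'   per-tree membership, per-tree observed flags) and edge table with
#'   membership.
#' @export
consensus_graph <- function(trees) {
  stopifnot(length(trees) >= 2L,
            all(vapply(trees, inherits, TRUE, "progression_tree")))
  pan <- trees[[1L]]$panel
  for (t in trees[-1L]) {
    if (!identical(probe_names(t$panel), probe_names(pan)) ||
        t$panel$max_copy != pan$max_copy) {
      stop("all trees must share one probe panel")
    }
  }
  k <- length(trees)
  keys <- sort(unique(unlist(lapply(trees, function(t) rownames(t$states)))))
  membership <- matrix(FALSE, length(keys), k,
                       dimnames = list(keys, NULL))
  observed <- membership
  for (ti in seq_len(k)) {
    t <- trees[[ti]]
    idx <- match(rownames(t$states), keys)
    membership[idx, ti] <- TRUE
    observed[idx, ti] <- !t$steiner
  }
  edge_tab <- unique(do.call(rbind, lapply(trees, tree_edge_keys)))
  ekey <- if (NROW(edge_tab) > 0L) paste(edge_tab[, 1L], edge_tab[, 2L], sep = "->")
          else character(0)
  ord <- order(ekey)
  edge_tab <- edge_tab[ord, , drop = FALSE]
  ekey <- ekey[ord]
  edge_membership <- matrix(FALSE, length(ekey), k, dimnames = list(ekey, NULL))
  for (ti in seq_len(k)) {
    te <- tree_edge_keys(trees[[ti]])
    if (NROW(te) > 0L) {
      edge_membership[match(paste(te[, 1L], te[, 2L], sep = "->"), ekey), ti] <- TRUE
    }
  }
  structure(
    list(panel = pan, keys = keys, states = keys_to_matrix(keys),
         membership = membership, observed = observed,
         edges = edge_tab, edge_membership = edge_membership,
         n_trees = k),
    class = "consensus_graph"
  )
}

#' @export
print.consensus_graph <- function(x, ...) {
  full <- sum(rowSums(x$membership) == x$n_trees)
  cat("Consensus graph over ", x$n_trees, " tree(s): ", length(x$keys),
      " node(s) (", full, " in all trees), ", NROW(x$edges), " edge(s)\n",
      sep = "")
  invisible(x)
}

#' @export
write_dot.consensus_graph <- function(x, path = NULL, ...) {
  id <- function(k) paste0("\"", k, "\"")
  lines <- c("digraph consensus {", "  node [shape=oval];")
  for (v in seq_along(x$keys)) {
    style <- if (!any(x$observed[v, ])) ", style=dashed" else ""
    shared <- sum(x$membership[v, ])
    lines <- c(lines, sprintf("  %s [label=\"%s\", penwidth=%d%s];",
                              id(x$keys[v]), x$keys[v], shared, style))
  }
  for (e in seq_len(NROW(x$edges))) {
    lines <- c(lines, sprintf("  %s -> %s [label=\"%d\"];",
                              id(x$edges[e, 1L]), id(x$edges[e, 2L]),
                              sum(x$edge_membership[e, ])))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# nodes of a tree reachable from the root through a restricted edge set
reachable_via_edges <- function(root_key, edge_tab) {
  seen <- root_key
  frontier <- root_key
  while (length(frontier) > 0L) {
    nxt <- edge_tab[edge_tab[, 1L] %in% frontier, 2L]
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Sharing statistics between two progression trees
#'
#' Quantifies how much of the observed cell-state space two trees (e.g. from
#' a paired primary/metastasis or in-situ/invasive design) have in common.
#' Three nested statistics are computed, each as an unweighted fraction of
#' observed states and as a cell-proportion-weighted fraction:
#' \itemize{
#'   \item `shared_nodes`: observed states present in both trees, over
#'     observed states present in either;
#'   \item `shared_reachable`: additionally reachable from the all-2 root
#'     within both trees;
#'   \item `shared_path`: additionally reachable from the root through a
#'     path whose every edge is present in both trees.
#' }
#' Steiner nodes never count as shared states but may mediate shared paths.
#' Weights pool the two samples: a pattern's mass is its total cell count in
#' both samples divided by the pooled number of cells.
#'
#' @param tA,tB `"progression_tree"` objects on the same panel.
#' @param dsA,dsB Optional [fish_data()] objects supplying cell counts for
#'   the weighted variants (default: counts stored on the trees).
#' @return A data.frame with columns `statistic`, `unweighted`, `weighted`.
#' @export
sharing_statistics <- function(tA, tB, dsA = NULL, dsB = NULL) {
  stopifnot(inherits(tA, "progression_tree"), inherits(tB, "progression_tree"))
  if (!identical(probe_names(tA$panel), probe_names(tB$panel))) {
    stop("trees must share one probe panel")
  }
  obsA <- rownames(tA$states)[!tA$steiner]
  obsB <- rownames(tB$states)[!tB$steiner]
  union_obs <- sort(union(obsA, obsB))
  shared <- intersect(obsA, obsB)
  root_key <- pattern_key(root_pattern(tA$panel))
  # reachability from the root within each tree (all nodes in a valid tree)
  reachA <- reachable_via_edges(root_key, tree_edge_keys(tA))
  reachB <- reachable_via_edges(root_key, tree_edge_keys(tB))
  shared_reach <- intersect(shared, intersect(reachA, reachB))
  # shared-path: reachable through edges present in both trees
  eA <- tree_edge_keys(tA)
  eB <- tree_edge_keys(tB)
  keyed <- function(e) paste(e[, 1L], e[, 2L], sep = "->")
  common_edges <- eA[keyed(eA) %in% keyed(eB), , drop = FALSE]
  shared_path <- intersect(shared, reachable_via_edges(root_key, common_edges))

  cells <- function(ds, tree) {
    if (is.null(ds)) {
      stats::setNames(tree$ncells, rownames(tree$states))
    } else {
      stats::setNames(ds$counts, rownames(ds$patterns))
    }
  }
  cA <- cells(dsA, tA)
  cB <- cells(dsB, tB)
  mass <- function(keys) {
    sum(cA[intersect(keys, names(cA))], cB[intersect(keys, names(cB))])
  }
  pooled <- mass(union_obs)
  frac <- function(keys) {
    if (length(union_obs) == 0L) return(1)
    length(keys) / length(union_obs)
  }
  wfrac <- function(keys) {
    if (pooled == 0) return(1)
    mass(keys) / pooled
  }
  data.frame(
    statistic = c("shared_nodes", "shared_reachable", "shared_path"),
    unweighted = c(frac(shared), frac(shared_reach), frac(shared_path)),
    weighted = c(wfrac(shared), wfrac(shared_reach), wfrac(shared_path)),
    stringsAsFactors = FALSE
  )
}
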