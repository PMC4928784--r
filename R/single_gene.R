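# --- copy-number state graphs over (ploidy, gene) ---------------------------
#
# A cn_graph holds a node set of patterns with observed/Steiner annotations
# and the directed edges between included nodes that are allowed transitions.
# Edge weights are derived on demand from a frequency distribution, so the
# same graph can be re-weighted across EM iterations.

cn_graph <- function(states, observed, ncells, panel) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  keys <- pattern_key(states)
  ord <- order(keys)
  states <- states[ord, , drop = FALSE]
  observed <- observed[ord]
  ncells <- ncells[ord]
  rownames(states) <- keys[ord]
  g <- list(states = states, observed = observed, ncells = ncells,
            panel = panel)
  g$edges <- graph_edges(g)
  class(g) <- "cn_graph"
  g
}

# all allowed transitions between included nodes: matrix(from, to) + event key
graph_edges <- function(g) {
  keys <- rownames(g$states)
  from <- integer(0); to <- integer(0); ev <- character(0)
  for (v in seq_len(nrow(g$states))) {
    tr <- allowed_transitions(g$states[v, ], g$panel)
    if (nrow(tr$states) == 0L) next
    succ <- pattern_key(tr$states)
    hit <- match(succ, keys)
    ok <- !is.na(hit)
    from <- c(from, rep.int(v, sum(ok)))
    to <- c(to, hit[ok])
    ev <- c(ev, rownames(tr$events)[ok])
  }
  list(from = from, to = to, event = ev)
}

#' @export
print.cn_graph <- function(x, ...) {
  cat("Copy-number graph: ", nrow(x$states), " node(s) (",
      sum(!x$observed), " unobserved), ", length(x$edges$from),
      " directed edge(s)\n", sep = "")
  invisible(x)
}

#' Graph of all possible (ploidy, gene) states
#'
#' Nodes are every in-bound state: ploidy `1..max_copy`, gene `0..max_copy`;
#' edges are all allowed transitions.
#'
#' @param panel A [probe_panel()] with exactly one gene probe.
#' @return A `"cn_graph"`.
#' @export
build_possible_graph <- function(panel) {
  stopifnot(n_genes(panel) == 1L)
  mc <- panel$max_copy
  states <- as.matrix(expand.grid(p = seq_len(mc), g = 0:mc))
  colnames(states) <- probe_names(panel)
  cn_graph(states, observed = rep(FALSE, nrow(states)),
           ncells = rep(0, nrow(states)), panel = panel)
}

#' Graph of observed (ploidy, gene) states
#'
#' Nodes are the observed patterns plus the all-2 root; edges are the allowed
#' transitions between included nodes.
#'
#' @param ds A [fish_data()] over one ploidy and one gene probe (see
#'   [marginalize()]).
#' @return A `"cn_graph"`.
#' @export
build_observed_graph <- function(ds) {
  stopifnot(inherits(ds, "fish_data"), n_genes(ds$panel) == 1L)
  keys <- rownames(ds$patterns)
  root <- root_pattern(ds$panel)
  rkey <- pattern_key(root)
  states <- ds$patterns
  ncells <- ds$counts
  observed <- rep(TRUE, nrow(states))
  if (!(rkey %in% keys)) {
    states <- rbind(states, root)
    ncells <- c(ncells, 0)
    observed <- c(observed, FALSE)
  }
  cn_graph(states, observed = observed, ncells = ncells, panel = ds$panel)
}

graph_root_index <- function(g) {
  match(pattern_key(root_pattern(g$panel)), rownames(g$states))
}

# nodes reachable from the root through directed edges
reachable_from_root <- function(g) {
  n <- nrow(g$states)
  seen <- logical(n)
  seen[graph_root_index(g)] <- TRUE
  frontier <- graph_root_index(g)
  while (length(frontier) > 0L) {
    nxt <- unique(g$edges$to[g$edges$from %in% frontier])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# initial frequencies: tally of edge types present in the observed graph;
# uniform when the graph has no edges
initial_frequencies <- function(g, floor = 1e-6) {
  if (length(g$edges$from) == 0L) return(uniform_frequencies(n_genes(g$panel)))
  normalize_tally(table(g$edges$event), n_genes(g$panel), floor)
}

#' Insert Steiner nodes to connect all observed states to the root
#'
#' Unobserved intermediate states are added along minimum-weight directed
#' paths (edge weight `-log p` under `freqs`) through the graph of all
#' possible states, from the set of states already reachable from the all-2
#' root to each unreachable observed state. Unreachable states are processed
#' in order of increasing path weight (ties broken lexicographically).
#'
#' @param g A `"cn_graph"` from [build_observed_graph()].
#' @param freqs Event frequencies used to weight candidate paths.
#' @return A `"cn_graph"` in which every observed node is reachable from the
#'   root; added nodes are flagged unobserved (Steiner).
#' @export
insert_steiner_nodes <- function(g, freqs) {
  panel <- g$panel
  pg <- build_possible_graph(panel)
  pg_keys <- rownames(pg$states)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = pg_keys[pg$edges$from], to = pg_keys[pg$edges$to]),
    directed = TRUE, vertices = pg_keys)
  wts <- event_weight(pg$edges$event, freqs)

  repeat {
    seen <- reachable_from_root(g)
    un <- which(g$observed & !seen)
    if (length(un) == 0L) break
    sources <- rownames(g$states)[seen]
    targets <- rownames(g$states)[un]
    d <- igraph::distances(ig, v = sources, to = targets, mode = "out",
                           weights = wts)
    best_per_target <- apply(d, 2L, min)
    # nearest target first; ties lexicographic by pattern key
    pick <- order(best_per_target, targets)[1L]
    src <- sources[which.min(d[, pick])]
    path <- igraph::shortest_paths(ig, from = src, to = targets[pick],
                                   mode = "out", weights = wts)$vpath[[1L]]
    path_keys <- names(path)
    new_keys <- setdiff(path_keys, rownames(g$states))
    if (length(new_keys) == 0L) {
      stop("internal error: no progress connecting ", targets[pick])
    }
    states <- rbind(g$states, keys_to_matrix(new_keys))
    g <- cn_graph(states,
                  observed = c(g$observed, rep(FALSE, length(new_keys))),
                  ncells = c(g$ncells, rep(0, length(new_keys))),
                  panel = panel)
  }
  g
}

#' Maximum-weight branching of a copy-number graph
#'
#' Finds the spanning arborescence rooted at the all-2 state that maximizes
#' the sum of `log p` over its edges (equivalently, the maximum-likelihood
#' spanning tree under the event model), using a Chu-Liu/Edmonds style
#' algorithm. Tie-breaks are lexicographic by (parent, child) pattern, so the
#' result is deterministic.
#'
#' @param g A `"cn_graph"` whose nodes are all reachable from the root (run
#'   [insert_steiner_nodes()] first).
#' @param freqs Event frequencies supplying edge probabilities.
#' @return A `"progression_tree"` spanning the graph's nodes.
#' @export
max_weight_branching <- function(g, freqs) {
  root <- graph_root_index(g)
  if (is.na(root)) stop("graph does not contain the all-2 root")
  if (!all(reachable_from_root(g))) {
    stop("graph has nodes unreachable from the root; insert Steiner nodes first")
  }
  n <- nrow(g$states)
  w <- -event_weight(g$edges$event, freqs)  # log p, maximized
  keys <- rownames(g$states)
  pref <- order(order(keys[g$edges$from], keys[g$edges$to]))
  ids <- seq_along(g$edges$from)
  sel <- max_branching_edges(n, g$edges$from, g$edges$to, w, ids, pref, root)
  parent_of <- rep(NA_integer_, n)
  parent_of[g$edges$to[sel]] <- g$edges$from[sel]
  branching_to_tree(g, parent_of, freqs)
}

# reorder nodes root-first and build a progression_tree from a parent map
branching_to_tree <- function(g, parent_of, freqs) {
  n <- nrow(g$states)
  root <- graph_root_index(g)
  ord <- c(root, setdiff(seq_len(n), root))
  inv <- match(seq_len(n), ord)
  progression_tree(g$states[ord, , drop = FALSE],
                   parent = ifelse(is.na(parent_of[ord]), NA_integer_,
                                   inv[parent_of[ord]]),
                   steiner = !g$observed[ord],
                   ncells = g$ncells[ord],
                   panel = g$panel, freqs = freqs)
}

#' Randomly perturb a branching
#'
#' Each non-root node's parent is, with probability `eps`, resampled among
#' its in-neighbors in the graph proportionally to event probability. The
#' perturbed parent map is then repaired to acyclicity by reverting nodes on
#' cycles (lexicographically smallest first) to their original parents. With
#' `eps = 0` the input tree is returned unchanged. The result is a valid
#' branching of the graph; randomness comes from the R RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param tree A `"progression_tree"` that is a branching of `g`.
#' @param g The `"cn_graph"` the tree spans.
#' @param freqs Event frequencies (sampling weights).
#' @param eps Per-node perturbation probability.
#' @return A `"progression_tree"`.
#' @export
randomize_branching <- function(tree, g, freqs, eps = 0.05) {
  if (eps <= 0) return(tree)
  keys <- rownames(g$states)
  tkeys <- rownames(tree$states)
  n <- nrow(g$states)
  root <- graph_root_index(g)
  # original parent map in graph indexing
  orig <- rep(NA_integer_, n)
  gi <- match(tkeys, keys)
  orig[gi[-1L]] <- gi[tree$parent[-1L]]
  parent_of <- orig
  probs_all <- exp(-event_weight(g$edges$event, freqs))
  for (v in seq_len(n)) {
    if (v == root) next
    if (stats::runif(1L) < eps) {
      idx <- which(g$edges$to == v & g$edges$from != v)
      if (length(idx) <= 1L) next
      pr <- probs_all[idx]
      parent_of[v] <- g$edges$from[sample(idx, 1L, prob = pr)]
    }
  }
  # repair cycles: revert perturbed nodes (lexicographically smallest first)
  # until acyclic; any cycle must contain a perturbed node since the
  # original parent map is acyclic, so this terminates
  repeat {
    cyc <- find_parent_cycle(parent_of, root)
    if (is.null(cyc)) break
    pert <- cyc[parent_of[cyc] != orig[cyc]]
    fix <- pert[order(keys[pert])][1L]
    parent_of[fix] <- orig[fix]
  }
  branching_to_tree(g, parent_of, freqs)
}

find_parent_cycle <- function(parent_of, root) {
  n <- length(parent_of)
  color <- integer(n)
  color[root] <- 2L
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- parent_of[v]
    }
    if (color[v] == 1L) {
      return(path[match(v, path):length(path)])
    }
    color[path] <- 2L
  }
  NULL
}

#' Fit a single-gene progression tree by EM over branchings
#'
#' Estimates, for one gene probe, both a rooted (ploidy, gene) progression
#' tree and the probability of each allowed event type. The dataset is
#' marginalized to the (ploidy, gene) pair; Steiner intermediates are
#' inserted along minimum-weight paths; then an EM loop alternates between
#' computing the maximum-weight branching under the current frequencies,
#' randomly perturbing it, and re-estimating frequencies as cell-count
#' weighted tallies of the perturbed branching's edge types (with a small
#' probability floor). The best-scoring branching encountered (by
#' self-consistent log-likelihood) over all restarts is returned, carrying
#' its tallied frequencies.
#'
#' @param ds A [fish_data()] object.
#' @param gene Name of the gene probe to model.
#' @param control A [ploidytree_control()] list (EM settings: `eps`, `tol`,
#'   `max_iter`, `restarts`, `floor`).
#' @return A `"progression_tree"` with the estimated event frequencies in
#'   `$freqs`.
#' @export
fit_gene_tree <- function(ds, gene, control = ploidytree_control()) {
  stopifnot(inherits(ds, "fish_data"))
  if (!(gene %in% ds$panel$genes)) stop("unknown gene probe: ", gene)
  dsm <- marginalize(ds, c(ds$panel$ploidy, gene))
  og <- build_observed_graph(dsm)
  freqs0 <- initial_frequencies(og, control$floor)
  og <- insert_steiner_nodes(og, freqs0)
  if (nrow(og$states) == 1L) {
    return(root_only_tree(og$panel, ncells = og$ncells,
                          freqs = uniform_frequencies(1L)))
  }
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(control$restarts)) {
    # every restart starts from the observed-graph tallies; restarts differ
    # only in the randomized-branching exploration stream (random
    # re-initialization was tried and found to push the EM into degenerate
    # concentrated fixed points that misestimate rates)
    freqs <- freqs0
    for (iter in seq_len(control$max_iter)) {
      B <- max_weight_branching(og, freqs)
      sc <- branching_score(B, control$floor)
      if (sc$score > best_score) {
        best_score <- sc$score
        best <- B
        best$freqs <- sc$freqs
      }
      Bp <- randomize_branching(B, og, freqs, control$eps)
      new_freqs <- em_update(Bp, control$floor)
      delta <- max(abs(new_freqs - freqs))
      freqs <- new_freqs
      if (delta < control$tol) break
    }
  }
  best
}

# edge-count tally of event types: each tree edge is one realized mutation
# event, so rates are estimated as the fraction of edges of each type
# (weighting by child cell counts would measure clonal expansion, not
# mutation rates, and badly biases gain/loss estimates)
em_update <- function(tree, floor = 1e-6) {
  n <- nrow(tree$states)
  tally <- numeric(0)
  for (v in seq_len(n)[-1L]) {
    key <- paste(tree$states[v, ] - tree$states[tree$parent[v], ],
                 collapse = ",")
    tally[key] <- (if (is.na(tally[key])) 0 else tally[key]) + 1
  }
  normalize_tally(tally, n_genes(tree$panel), floor)
}

# self-consistent log-likelihood: tree scored under its own tallied freqs
branching_score <- function(tree, floor = 1e-6) {
  freqs <- em_update(tree, floor)
  score <- 0
  for (v in seq_len(nrow(tree$states))[-1L]) {
    key <- paste(tree$states[v, ] - tree$states[tree$parent[v], ],
                 collapse = ",")
    score <- score + log(freqs[key])
  }
  list(score = unname(score), freqs = freqs)
}
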