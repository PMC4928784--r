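#' Event-rate profiles used in the package's validation studies
#'
#' Three probability distributions over the eight allowed event types for a
#' panel of one ploidy probe and two gene probes. They span the regimes the
#' simulator is exercised in: profile 1 is dominated by gain of the second
#' gene with substantial loss of the first; profile 2 concentrates almost
#' half its mass on gain of the second gene; profile 3 spreads mass more
#' evenly over single-gene gains and losses. Each vector is normalized to
#' sum to one.
#'
#' @return Named list of three named frequency vectors (`profile1`,
#'   `profile2`, `profile3`), keyed by event delta.
#' @export
validation_rates <- function() {
  keys <- c("-1,-1,-1", "-1,0,0", "0,-1,0", "0,0,-1",
            "0,0,1", "0,1,0", "1,0,0", "1,1,1")
  mk <- function(v) {
    x <- stats::setNames(v, keys)
    x / sum(x)
  }
  list(
    profile1 = mk(c(0.0147, 0.00139, 0.298, 0.0355, 0.379, 0.0294, 0.0161, 0.226)),
    profile2 = mk(c(0.0177, 0.00168, 0.203, 0.0502, 0.483, 0.0228, 0.0286, 0.193)),
    profile3 = mk(c(0.0123, 0.000929, 0.196, 0.187, 0.211, 0.224, 0.0213, 0.147))
  )
}

#' Simulate a random progression tree under the event model
#'
#' Grows a tree from the all-2 root: repeatedly choose an existing node
#' uniformly at random, draw an event type from `rates`, and add the
#' resulting child state if it is within bounds and not already in the tree,
#' until `n_nodes` distinct states exist. Every edge is one allowed event
#' type; node states are unique. Randomness uses the R RNG (seed with
#' [set.seed()]).
#'
#' @param rates Named frequency vector over the allowed event types of the
#'   panel (see [validation_rates()]).
#' @param n_nodes Number of distinct states to grow (default 38).
#' @param panel A [probe_panel()]; defaults to one ploidy probe and two gene
#'   probes with `max_copy` 9.
#' @return A `"progression_tree"` (all nodes flagged observed with 0 cells;
#'   attach counts with [simulate_cells()]).
#' @export
simulate_tree <- function(rates, n_nodes = 38L,
                          panel = probe_panel("ploidy", c("g1", "g2"))) {
  ng <- n_genes(panel)
  check_frequencies(rates, ng)
  ev <- event_types(ng)
  rates <- rates[rownames(ev)]
  states <- matrix(root_pattern(panel), 1L)
  keys <- pattern_key(states[1L, ])
  parent <- NA_integer_
  attempts <- 0L
  max_attempts <- 10000L * n_nodes
  while (nrow(states) < n_nodes) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("simulate_tree failed to reach ", n_nodes,
           " nodes; rates may make most states unreachable")
    }
    v <- sample.int(nrow(states), 1L)
    d <- ev[sample.int(nrow(ev), 1L, prob = rates), ]
    child <- states[v, ] + d
    if (child[1L] < 1L || any(child < 0L) || any(child > panel$max_copy)) next
    ck <- pattern_key(child)
    if (ck %in% keys) next
    states <- rbind(states, child)
    keys <- c(keys, ck)
    parent <- c(parent, v)
  }
  progression_tree(states, parent, steiner = rep(FALSE, nrow(states)),
                   ncells = rep(0, nrow(states)), panel = panel,
                   freqs = rates)
}

#' Realized event-type rates of a tree
#'
#' The normalized tally of edge event types actually present in a tree. For
#' simulated trees this is the "actual" distribution that inference is
#' compared against: the realized edge mix differs from the input rates
#' because out-of-bound and duplicate states are rejected during growth.
#'
#' @param tree A `"progression_tree"` whose edges are single allowed events.
#' @return Named frequency vector over all allowed event types (zeros kept,
#'   no floor).
#' @export
realized_rates <- function(tree) {
  ev <- event_types(n_genes(tree$panel))
  out <- stats::setNames(rep(0, nrow(ev)), rownames(ev))
  tally <- tree_event_tally(tree)
  out[names(tally)] <- tally
  if (sum(out) > 0) out <- out / sum(out)
  out
}

#' Sample a single-cell dataset from a tree
#'
#' Draws node proportions from a flat Dirichlet distribution and assigns
#' `n_cells` cells multinomially to the tree's states. States receiving no
#' cells are simply absent from the dataset (they become candidates for
#' Steiner inference).
#'
#' @param tree A `"progression_tree"`.
#' @param n_cells Number of cells to sample (default 250).
#' @return A [fish_data()] whose every pattern is a node of `tree`.
#' @export
simulate_cells <- function(tree, n_cells = 250L) {
  n <- nrow(tree$states)
  prop <- stats::rgamma(n, 1)          # Dirichlet(1, ..., 1)
  prop <- prop / sum(prop)
  counts <- as.integer(stats::rmultinom(1L, n_cells, prop))
  keep <- counts > 0L
  fish_data(tree$states[keep, , drop = FALSE], counts[keep], tree$panel)
}

#' Run a simulation study of the full inference pipeline
#'
#' For each replicate: grow a random true tree, sample a single-cell dataset
#' from it, fit one single-gene tree per gene probe by EM, and merge the
#' single-gene trees with the MILP (all merge instances are solved in one
#' batched backend call). Returns per-replicate evaluation records and the
#' pooled predicted/actual event-rate comparison.
#'
#' @param rates Input event rates for the simulator (see
#'   [validation_rates()]).
#' @param n_trees Number of replicates (default 100).
#' @param n_nodes Nodes per simulated tree (default 38).
#' @param n_cells Cells per sampled dataset (default 250).
#' @param panel Probe panel (default: ploidy + two genes, `max_copy` 9).
#' @param control A [ploidytree_control()].
#' @param seed Optional seed applied with [set.seed()]; one seed drives all
#'   randomness in the study.
#' @return An object of class `"simulation_study"`: `records` (one row per
#'   replicate: reconstruction error `r_percent`, `tree_weight`,
#'   `avg_edge_weight`, `steiner_fraction`, `coverage`, `expected_depth`,
#'   `shannon_entropy`, `simpson_index`), `predicted` and `actual` pooled
#'   rate vectors, `w` (pooled parameter-recovery statistic), and
#'   `instances` (true tree, dataset, merged tree per replicate).
#' @export
run_simulation_study <- function(rates, n_trees = 100L, n_nodes = 38L,
                                 n_cells = 250L,
                                 panel = probe_panel("ploidy", c("g1", "g2")),
                                 control = ploidytree_control(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes(panel) >= 2L)
  truths <- vector("list", n_trees)
  datasets <- vector("list", n_trees)
  problems <- vector("list", n_trees)
  partials <- vector("list", n_trees)  # trees already merged when > 2 genes
  for (r in seq_len(n_trees)) {
    truths[[r]] <- simulate_tree(rates, n_nodes, panel)
    datasets[[r]] <- simulate_cells(truths[[r]], n_cells)
    gene_trees <- lapply(panel$genes, function(g)
      fit_gene_tree(datasets[[r]], g, control))
    # fold all but the last merge eagerly; batch the final (dominant) merge
    acc <- gene_trees[[1L]]
    for (k in seq_along(gene_trees)[-1L]) {
      pr <- build_merge_problem(acc, gene_trees[[k]], datasets[[r]],
                                rho = control$rho, sigma = control$sigma,
                                tau = control$tau)
      if (k < length(gene_trees)) {
        acc <- solve_merge(pr, control)$tree
      } else {
        problems[[r]] <- pr
      }
    }
    partials[[r]] <- acc
  }
  solutions <- solve_merge_batch(problems, control)
  merged <- lapply(solutions, `[[`, "tree")

  records <- do.call(rbind, lapply(seq_len(n_trees), function(r) {
    tr <- merged[[r]]
    data.frame(
      replicate = r,
      r_percent = reconstruction_error(truths[[r]], tr),
      tree_weight = tree_weight(tr),
      avg_edge_weight = avg_edge_weight(tr),
      steiner_fraction = steiner_fraction(tr),
      coverage = coverage(tr, datasets[[r]]),
      expected_depth = expected_depth(tr),
      shannon_entropy = shannon_entropy(tr$freqs),
      simpson_index = simpson_index(tr$freqs)
    )
  }))

  pool <- function(trees) {
    tot <- numeric(0)
    for (t in trees) {
      tl <- tree_event_tally(t)
      for (k in names(tl)) {
        tot[k] <- (if (is.na(tot[k])) 0 else tot[k]) + tl[k]
      }
    }
    ev <- event_types(n_genes(panel))
    out <- stats::setNames(rep(0, nrow(ev)), rownames(ev))
    out[names(tot)] <- tot
    out / sum(out)
  }
  predicted <- pool(merged)
  actual <- pool(truths)

  sup <- actual > 0  # small studies can miss a rare type entirely
  structure(
    list(records = records,
         predicted = predicted, actual = actual,
         w = w_statistic(predicted[sup], actual[sup]),
         instances = list(true_trees = truths, datasets = datasets,
                          merged_trees = merged),
         rates = rates, n_trees = n_trees, n_nodes = n_nodes,
         n_cells = n_cells),
    class = "simulation_study"
  )
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("Simulation study: ", x$n_trees, " replicate(s), ", x$n_nodes,
      " nodes/tree, ", x$n_cells, " cells/sample\n", sep = "")
  cat(sprintf("  pooled W = %.4f; mean R = %.2f%%; mean tree weight = %.2f\n",
              x$w, mean(x$records$r_percent), mean(x$records$tree_weight)))
  cat(sprintf("  mean avg edge weight = %.3f; mean Steiner fraction = %.3f; mean coverage = %.3f\n",
              mean(x$records$avg_edge_weight), mean(x$records$steiner_fraction),
              mean(x$records$coverage)))
  invisible(x)
}
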