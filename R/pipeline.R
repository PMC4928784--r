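#' Fit a ploidy-based progression tree to a single-cell FISH sample
#'
#' The main fitting function. For each requested gene probe a single-gene
#' (ploidy, gene) progression tree is estimated by EM over maximum-weight
#' branchings ([fit_gene_tree()]); the single-gene trees are then merged
#' into one joint tree over all probes by sequentially solving the
#' tree-merging MILP ([solve_merge()]). The returned object carries the
#' fitted trees, the final merge solution, the event-type frequencies
#' inferred from the joint tree, and summary statistics.
#'
#' @param data A [fish_data()] object (see [read_fish_data()]).
#' @param genes Gene probes to model (default: all in the panel, in panel
#'   order, which is also the merge order).
#' @param control A [ploidytree_control()].
#' @param seed Optional integer; when given, [set.seed()] is called so the
#'   whole fit is reproducible.
#' @return An object of class `"ploidytree"` with components `tree` (the
#'   merged `"progression_tree"`), `gene_trees`, `solution` (final
#'   `"merge_solution"`, `NULL` for a single gene), `problem`, `data`,
#'   `stats`, `control`, and `call`.
#' @examples
#' \donttest{
#' pan <- probe_panel("cep", c("gA", "gB"))
#' ds <- fish_data(rbind(c(2, 2, 2), c(2, 3, 2), c(2, 3, 3)),
#'                 c(60, 25, 15), pan)
#' fit <- ploidytree(ds, seed = 1)
#' summary(fit)
#' }
#' @export
ploidytree <- function(data, genes = NULL, control = ploidytree_control(),
                       seed = NULL) {
  stopifnot(inherits(data, "fish_data"))
  if (!is.null(seed)) set.seed(seed)
  panel <- data$panel
  if (is.null(genes)) genes <- panel$genes
  if (!all(genes %in% panel$genes)) {
    stop("unknown gene probe(s): ",
         paste(setdiff(genes, panel$genes), collapse = ", "))
  }
  gene_trees <- lapply(genes, function(g) fit_gene_tree(data, g, control))
  names(gene_trees) <- genes

  solution <- NULL
  problem <- NULL
  if (length(genes) == 1L) {
    merged <- gene_trees[[1L]]
  } else {
    acc <- gene_trees[[1L]]
    for (k in seq_along(genes)[-1L]) {
      problem <- build_merge_problem(acc, gene_trees[[k]], data,
                                     rho = control$rho, sigma = control$sigma,
                                     tau = control$tau)
      res <- solve_merge(problem, control)
      acc <- res$tree
      solution <- res$solution
    }
    merged <- acc
  }
  dsu <- marginalize(data, c(panel$ploidy, genes))
  stats <- list(
    coverage = coverage(merged, dsu),
    steiner_fraction = steiner_fraction(merged),
    tree_weight = tree_weight(merged),
    avg_edge_weight = if (n_edges(merged) > 0L) avg_edge_weight(merged) else NA_real_,
    expected_depth = expected_depth(merged, dsu),
    shannon_entropy = shannon_entropy(merged$freqs),
    simpson_index = simpson_index(merged$freqs)
  )
  structure(
    list(tree = merged, gene_trees = gene_trees, solution = solution,
         problem = problem, data = data, genes = genes, stats = stats,
         control = control, call = match.call()),
    class = "ploidytree"
  )
}

#' @export
print.ploidytree <- function(x, ...) {
  cat("Ploidy-based progression tree fit\n")
  cat("  sample: ", nrow(x$data$patterns), " pattern(s), ",
      total_cells(x$data), " cells; genes: ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  cat("  merged tree: ", nrow(x$tree$states), " node(s) (",
      sum(x$tree$steiner), " Steiner), coverage ",
      sprintf("%.3f", x$stats$coverage), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ploidytree <- function(object, ...) {
  structure(list(fit = object), class = "summary.ploidytree")
}

#' @export
print.summary.ploidytree <- function(x, ...) {
  f <- x$fit
  print(f)
  s <- f$stats
  cat(sprintf("  tree weight %.3f (avg/edge %.3f)\n",
              s$tree_weight, s$avg_edge_weight))
  cat(sprintf("  expected depth %.3f; Shannon entropy %.3f; Simpson index %.3f\n",
              s$expected_depth, s$shannon_entropy, s$simpson_index))
  cat("  event frequencies (top 5):\n")
  top <- sort(f$tree$freqs, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  for (k in names(top)) cat(sprintf("    (%s)  %.4f\n", k, top[k]))
  invisible(x)
}

#' @export
coef.ploidytree <- function(object, ...) {
  object$tree$freqs
}

#' @export
logLik.ploidytree <- function(object, ...) {
  val <- -object$stats$tree_weight
  attr(val, "df") <- length(object$tree$freqs) - 1L
  attr(val, "nobs") <- total_cells(object$data)
  class(val) <- "logLik"
  val
}

#' @export
plot.ploidytree <- function(x, ...) {
  plot(x$tree, ...)
}

#' Frequency residuals of the final merge
#'
#' The difference `p - q` between observed joint-state frequencies and the
#' model frequencies assigned by the merge MILP, one entry per (tree-A node,
#' tree-B node) pair of the final merge. Nonzero residuals are where the
#' sigma penalty was paid.
#'
#' @param object A `"ploidytree"` fit.
#' @param ... Unused.
#' @return Numeric matrix, or `NULL` for single-gene fits.
#' @export
residuals.ploidytree <- function(object, ...) {
  if (is.null(object$solution)) return(NULL)
  object$problem$p - object$solution$q
}

#' Simulate datasets from a fitted progression tree
#'
#' Draws new single-cell samples from the fitted tree's observed cell
#' proportions (multinomial at the original sample size).
#'
#' @param object A `"ploidytree"` fit.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of [fish_data()] objects.
#' @export
simulate.ploidytree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tree <- object$tree
  tot <- sum(tree$ncells)
  prob <- tree$ncells / tot
  lapply(seq_len(nsim), function(i) {
    counts <- as.integer(stats::rmultinom(1L, tot, prob))
    keep <- counts > 0L
    fish_data(tree$states[keep, , drop = FALSE], counts[keep], tree$panel)
  })
}

#' Paired-sample analysis
#'
#' Fits a progression tree to each of two samples from the same patient
#' (e.g. primary/metastasis or in-situ/invasive), builds their consensus
#' graph, and computes the sharing statistics.
#'
#' @param dsA,dsB [fish_data()] objects on the same panel.
#' @param genes Gene probes to model (default: all).
#' @param control A [ploidytree_control()].
#' @param seed Optional seed covering both fits.
#' @return A list of class `"ploidytree_paired"`: `fitA`, `fitB`,
#'   `consensus` (a `"consensus_graph"`), `stats` (sharing statistics
#'   data.frame).
#' @export
ploidytree_paired <- function(dsA, dsB, genes = NULL,
                              control = ploidytree_control(), seed = NULL) {
  if (!identical(probe_names(dsA$panel), probe_names(dsB$panel))) {
    stop("samples must share one probe panel")
  }
  if (!is.null(seed)) set.seed(seed)
  fitA <- ploidytree(dsA, genes, control)
  fitB <- ploidytree(dsB, genes, control)
  structure(
    list(fitA = fitA, fitB = fitB,
         consensus = consensus_graph(list(fitA$tree, fitB$tree)),
         stats = sharing_statistics(fitA$tree, fitB$tree, dsA = NULL, dsB = NULL)),
    class = "ploidytree_paired"
  )
}

#' @export
print.ploidytree_paired <- function(x, ...) {
  cat("Paired progression-tree analysis\n")
  print(x$consensus)
  print(x$stats, row.names = FALSE)
  invisible(x)
}
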