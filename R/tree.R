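#' Rooted copy-number progression trees
#'
#' A progression tree is a rooted directed tree over cell-count patterns. The
#' root is always the all-2 wild-type state; every other node has exactly one
#' parent and is reachable from the root. Nodes are flagged observed or
#' Steiner (an unobserved state inserted as a biologically necessary or
#' likely intermediate) and carry the number of cells observed in that state.
#' Edges represent mutation events; in multi-probe trees an edge's raw
#' copy-number change may be composite and is interpreted through
#' [decompose_edge()].
#'
#' @param states Integer matrix of node patterns, one row per node; row 1
#'   must be the all-2 root.
#' @param parent Integer vector of parent row indices (`NA` for the root).
#' @param steiner Logical vector: is each node an unobserved Steiner node?
#' @param ncells Numeric vector of observed cell counts per node.
#' @param panel A [probe_panel()].
#' @param freqs Optional event-type frequency distribution attached to the
#'   tree (used for edge weights and probabilities).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `"progression_tree"`.
#' @export
progression_tree <- function(states, parent, steiner = NULL, ncells = NULL,
                             panel, freqs = NULL, validate = TRUE) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  n <- nrow(states)
  if (is.null(steiner)) steiner <- rep(FALSE, n)
  if (is.null(ncells)) ncells <- rep(0, n)
  rownames(states) <- pattern_key(states)
  tree <- structure(
    list(states = states, parent = as.integer(parent),
         steiner = as.logical(steiner), ncells = as.numeric(ncells),
         panel = panel, freqs = freqs),
    class = "progression_tree"
  )
  if (validate) validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  states <- tree$states
  n <- nrow(states)
  panel <- tree$panel
  if (n < 1L) stop("tree must have at least one node")
  if (ncol(states) != n_genes(panel) + 1L) stop("state width does not match panel")
  if (!identical(unname(states[1L, ]), root_pattern(panel))) {
    stop("root (node 1) must be the all-2 pattern")
  }
  if (anyDuplicated(rownames(states))) stop("duplicate node patterns")
  if (length(tree$parent) != n || !is.na(tree$parent[1L])) {
    stop("root must have no parent; one parent entry per node")
  }
  if (n > 1L) {
    p <- tree$parent[-1L]
    if (any(is.na(p)) || any(p < 1L) || any(p > n)) {
      stop("every non-root node needs a valid parent index")
    }
  }
  # reachability from root (and hence acyclicity of the parent map)
  depth <- tree_depths(tree, check = TRUE)
  if (any(is.na(depth))) stop("node(s) not reachable from the root")
  # every edge must decompose into allowed events
  for (v in seq_len(n)[-1L]) {
    dec <- decompose_edge(states[tree$parent[v], ], states[v, ])
    if (is.null(dec)) {
      stop("edge into (", rownames(states)[v],
           ") has a ploidy change of magnitude >= 2")
    }
  }
  invisible(TRUE)
}

# depth per node (root = 0); NA / error on cycles
tree_depths <- function(tree, check = FALSE) {
  n <- nrow(tree$states)
  depth <- rep(NA_real_, n)
  depth[1L] <- 0
  for (v in seq_len(n)[-1L]) {
    u <- v
    chain <- integer(0)
    while (is.na(depth[u])) {
      chain <- c(chain, u)
      u <- tree$parent[u]
      if (is.na(u)) break
      if (length(chain) > n) {
        if (check) stop("cycle in parent map") else return(depth)
      }
    }
    if (!is.na(u)) depth[chain] <- depth[u] + seq(length(chain), 1L)
  }
  depth
}

n_edges <- function(tree) nrow(tree$states) - 1L

root_only_tree <- function(panel, ncells = 0, freqs = NULL) {
  progression_tree(matrix(root_pattern(panel), 1L), NA_integer_,
                   steiner = FALSE, ncells = ncells, panel = panel,
                   freqs = freqs)
}

# edges as a two-column key matrix (parent_key, child_key)
tree_edge_keys <- function(tree) {
  n <- nrow(tree$states)
  if (n < 2L) return(matrix(character(), 0L, 2L))
  cbind(rownames(tree$states)[tree$parent[-1L]], rownames(tree$states)[-1L])
}

# probability of the edge into node v = product over its decomposed events
edge_probability <- function(tree, v, freqs = tree$freqs) {
  if (is.null(freqs)) return(NA_real_)
  dec <- decompose_edge(tree$states[tree$parent[v], ], tree$states[v, ])
  prod(vapply(dec, function(d) unname(freqs[paste(d, collapse = ",")]), 0))
}

#' @export
print.progression_tree <- function(x, ...) {
  cat("Progression tree: ", nrow(x$states), " node(s) (",
      sum(x$steiner), " Steiner), ", n_edges(x), " edge(s), root ",
      rownames(x$states)[1L], ", probes: ",
      paste(probe_names(x$panel), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Emit a tree or consensus graph in DOT format
#'
#' Produces GraphViz DOT text: node labels are comma-separated copy-number
#' patterns, Steiner nodes are drawn as dashed ovals, and each edge is
#' labeled with its event probability to three decimals (when frequencies
#' are attached).
#'
#' @param x A `"progression_tree"` or `"consensus_graph"`.
#' @param path Optional file to write to.
#' @param ... Unused.
#' @return The DOT text as a character scalar (invisibly when `path` given).
#' @export
write_dot <- function(x, path = NULL, ...) UseMethod("write_dot")

#' @export
write_dot.progression_tree <- function(x, path = NULL, ...) {
  keys <- rownames(x$states)
  id <- function(k) paste0("\"", k, "\"")
  lines <- c("digraph progression {", "  node [shape=oval];")
  for (v in seq_along(keys)) {
    style <- if (x$steiner[v]) ", style=dashed" else ""
    lines <- c(lines, sprintf("  %s [label=\"%s\"%s];", id(keys[v]), keys[v], style))
  }
  for (v in seq_along(keys)[-1L]) {
    p <- edge_probability(x, v)
    lab <- if (is.na(p)) "" else sprintf(" [label=\"%.3f\"]", p)
    lines <- c(lines, sprintf("  %s -> %s%s;", id(keys[x$parent[v]]), id(keys[v]), lab))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Serialize a progression tree to JSON text
#'
#' Lossless structured-text round trip for trees: nodes (pattern, Steiner
#' flag, observed cell count), edges, panel, and any attached event
#' frequencies, under a versioned schema.
#'
#' @param tree A `"progression_tree"`.
#' @return JSON text (character scalar).
#' @seealso [deserialize_tree()], [write_tree_json()]
#' @export
serialize_tree <- function(tree) {
  keys <- rownames(tree$states)
  obj <- list(
    schema = "ploidytree/1",
    panel = list(ploidy = tree$panel$ploidy, genes = tree$panel$genes,
                 max_copy = tree$panel$max_copy),
    nodes = {
      df <- data.frame(pattern = keys, steiner = tree$steiner,
                       ncells = tree$ncells, stringsAsFactors = FALSE)
      if (!is.null(tree$edge_weight)) df$edge_weight <- tree$edge_weight
      df
    },
    edges = if (n_edges(tree) > 0L) {
      data.frame(parent = keys[tree$parent[-1L]], child = keys[-1L],
                 stringsAsFactors = FALSE)
    } else data.frame(parent = character(), child = character()),
    freqs = as.list(tree$freqs)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Restore a progression tree from JSON text
#'
#' Validates all tree invariants on the way in; tampered input (e.g. an edge
#' referencing a missing node) is rejected.
#'
#' @param txt JSON text produced by [serialize_tree()].
#' @return A `"progression_tree"`.
#' @export
deserialize_tree <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
  if (!identical(obj$schema, "ploidytree/1")) {
    stop("unknown tree schema version: ", format(obj$schema))
  }
  panel <- probe_panel(obj$panel$ploidy, unlist(obj$panel$genes), obj$panel$max_copy)
  keys <- obj$nodes$pattern
  states <- keys_to_matrix(keys)
  parent <- rep(NA_integer_, length(keys))
  if (NROW(obj$edges) > 0L) {
    pi <- match(obj$edges$parent, keys)
    ci <- match(obj$edges$child, keys)
    if (any(is.na(pi)) || any(is.na(ci))) {
      stop("validation error: edge references a missing node")
    }
    parent[ci] <- pi
  }
  # root must be first; serialized trees always store it first
  freqs <- if (length(obj$freqs)) unlist(obj$freqs) else NULL
  tree <- progression_tree(states, parent, steiner = obj$nodes$steiner,
                           ncells = obj$nodes$ncells, panel = panel,
                           freqs = freqs)
  if (!is.null(obj$nodes$edge_weight)) tree$edge_weight <- obj$nodes$edge_weight
  tree
}

#' Read/write a progression tree as a JSON file
#'
#' @param tree A `"progression_tree"`.
#' @param path File path.
#' @return `read_tree_json()` returns the tree; `write_tree_json()` returns
#'   `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  writeLines(serialize_tree(tree), path)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  deserialize_tree(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Plot a progression tree
#'
#' Simple base-graphics rendering: nodes laid out by depth, Steiner nodes
#' dashed, labels are copy-number patterns.
#'
#' @param x A `"progression_tree"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.progression_tree <- function(x, ...) {
  n <- nrow(x$states)
  depth <- tree_depths(x)
  # order leaves within depth by pattern for a stable layout
  xs <- numeric(n)
  for (d in sort(unique(depth))) {
    idx <- which(depth == d)
    idx <- idx[order(rownames(x$states)[idx])]
    xs[idx] <- seq_along(idx) / (length(idx) + 1)
  }
  ys <- -depth
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0, 1), ylim = range(ys) + c(-0.5, 0.5), ...)
  for (v in seq_len(n)[-1L]) {
    graphics::segments(xs[x$parent[v]], ys[x$parent[v]], xs[v], ys[v],
                       col = "grey50")
  }
  graphics::points(xs, ys, pch = ifelse(x$steiner, 1, 16),
                   cex = 1.2, col = ifelse(x$steiner, "grey40", "black"))
  graphics::text(xs, ys, rownames(x$states), pos = 3, cex = 0.7)
  invisible(x)
}
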