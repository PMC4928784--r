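# Maximum-weight arborescence (branching) with a fixed root, in the
# Chu-Liu/Edmonds family: repeatedly select the best in-edge per node,
# contract any cycle, and expand. Weights are maximized. Ties are broken by
# the caller-supplied preference rank (lower wins), which the package sets to
# the lexicographic (parent, child) pattern order so results are reproducible.
#
# from/to: integer endpoints (1..n_nodes); w: weights; id: stable edge ids;
# pref: tie-break rank. Returns ids of the selected edges (one per non-root).
max_branching_edges <- function(n_nodes, from, to, w, id, pref, root) {
  stopifnot(length(from) == length(to), length(w) == length(from))
  if (n_nodes == 1L) return(integer(0))

  best <- rep(NA_integer_, n_nodes)  # row index of chosen in-edge per node
  for (v in seq_len(n_nodes)) {
    if (v == root) next
    idx <- which(to == v & from != v)
    if (length(idx) == 0L) {
      stop("node ", v, " has no in-edge: not reachable from the root")
    }
    mx <- max(w[idx])
    cand <- idx[w[idx] == mx]
    best[v] <- cand[which.min(pref[cand])]
  }

  # cycle detection on the chosen-parent map
  color <- integer(n_nodes)  # 0 unvisited, 2 settled
  color[root] <- 2L
  cyc <- NULL
  for (s in seq_len(n_nodes)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- from[best[v]]
    }
    if (color[v] == 1L) {           # walked back into the current path
      i <- match(v, path)
      cyc <- path[i:length(path)]
      color[path] <- 2L
      break
    }
    color[path] <- 2L
  }

  if (is.null(cyc)) {
    return(id[best[setdiff(seq_len(n_nodes), root)]])
  }

  # contract the cycle into one super node
  inC <- logical(n_nodes)
  inC[cyc] <- TRUE
  map <- integer(n_nodes)
  map[!inC] <- seq_len(n_nodes - length(cyc))
  cnode <- n_nodes - length(cyc) + 1L
  map[inC] <- cnode

  keep <- !(inC[from] & inC[to])
  nf <- map[from[keep]]
  nt <- map[to[keep]]
  nw <- w[keep]
  adj <- inC[to[keep]]              # edges entering the cycle get adjusted weight
  nw[adj] <- nw[adj] - w[best[to[keep][adj]]]
  sel <- max_branching_edges(cnode, nf, nt, nw, id[keep], pref[keep], map[root])

  pos <- match(sel, id)
  enters <- inC[to[pos]]
  t_star <- to[pos[enters]]         # cycle node where the external edge enters
  c(sel, id[best[cyc[cyc != t_star]]])
}
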