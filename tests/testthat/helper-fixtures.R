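# shared fixture builders; everything is generated in code at test time

toy_panel <- function(max_copy = 9L) probe_panel("cep", c("gA", "gB"), max_copy)

single_panel <- function(max_copy = 9L) probe_panel("cep", "gA", max_copy)

# write a per-cell or pattern+count TSV and return its path
write_tsv_fixture <- function(lines, header) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(header, lines), path)
  path
}

# small hand-built progression tree over (cep, gA, gB)
chain_tree <- function(panel = toy_panel(), ncells = NULL) {
  states <- rbind(c(2, 2, 2), c(2, 2, 3), c(2, 2, 4))
  if (is.null(ncells)) ncells <- c(10, 5, 5)
  progression_tree(states, c(NA, 1L, 2L), steiner = rep(FALSE, 3),
                   ncells = ncells, panel = panel)
}

# random single-gene dataset drawn from a random single-gene tree
random_single_gene_data <- function(n_nodes = 8L, n_cells = 120L,
                                    panel = single_panel()) {
  rates <- uniform_frequencies(1L)
  tree <- simulate_tree(rates, n_nodes, panel)
  simulate_cells(tree, n_cells)
}

# brute-force maximum-weight arborescence: enumerate all parent assignments
brute_force_branching <- function(n, from, to, w, root) {
  in_edges <- lapply(seq_len(n), function(v) which(to == v & from != v))
  best <- -Inf
  rec <- function(v, chosen, total) {
    if (v > n) {
      parent <- rep(NA_integer_, n)
      parent[to[chosen]] <- from[chosen]
      # acyclic iff all nodes reach the root
      for (s in seq_len(n)) {
        u <- s
        steps <- 0L
        while (!is.na(parent[u])) {
          u <- parent[u]
          steps <- steps + 1L
          if (steps > n) return(invisible(NULL))
        }
        if (u != root) return(invisible(NULL))
      }
      if (total > best) best <<- total
      return(invisible(NULL))
    }
    if (v == root) {
      rec(v + 1L, chosen, total)
    } else {
      for (e in in_edges[[v]]) rec(v + 1L, c(chosen, e), total + w[e])
    }
    invisible(NULL)
  }
  rec(1L, integer(0), 0)
  best
}

# total weight of a progression tree under log-probability edge weights
branching_logp <- function(tree, freqs) {
  s <- 0
  for (v in seq_len(nrow(tree$states))[-1L]) {
    key <- paste(tree$states[v, ] - tree$states[tree$parent[v], ],
                 collapse = ",")
    s <- s + log(freqs[key])
  }
  unname(s)
}

# random connected weighted digraph over <= n_max nodes for branching tests
random_branching_graph <- function(n_max = 6L) {
  n <- sample(2:n_max, 1L)
  root <- 1L
  from <- integer(0); to <- integer(0)
  # random spanning structure ensures reachability, then extra random edges
  for (v in 2:n) {
    from <- c(from, sample(seq_len(v - 1L), 1L))
    to <- c(to, v)
  }
  extra <- sample(0:(n * 2L), 1L)
  for (k in seq_len(extra)) {
    u <- sample(n, 1L); v <- sample(n, 1L)
    if (u != v && v != root && !any(from == u & to == v)) {
      from <- c(from, u); to <- c(to, v)
    }
  }
  list(n = n, from = from, to = to,
       w = round(stats::runif(length(from), -2, 2), 3), root = root)
}
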