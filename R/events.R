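#' Allowed mutation event types
#'
#' The model restricts single-step copy-number changes between two cell states
#' `(p, g1, ..., gn)` to three families of events:
#' \itemize{
#'   \item gain or loss of one copy of a single gene probe (ploidy unchanged);
#'   \item gain or loss of one ploidy copy with no gene change, modeling a
#'     chromosome missegregation that shifts the modal chromosome number but
#'     not the chromosome carrying any gene probe;
#'   \item concerted gain or loss of one ploidy copy together with all gene
#'     probes in the same direction.
#' }
#' For one gene probe this yields the six classic transitions; for `n` genes
#' there are `2n + 4` event types. Events are represented as integer delta
#' vectors in `{-1, 0, +1}^(n+1)` (ploidy component first) and keyed by their
#' comma-separated form, e.g. `"0,0,1"`.
#'
#' @param n_genes Number of gene probes.
#' @return Integer matrix of allowed deltas, one row per event type, in
#'   lexicographic order; row names are the event keys.
#' @export
event_types <- function(n_genes) {
  n <- as.integer(n_genes)
  stopifnot(n >= 1L)
  ev <- list(rep(-1L, n + 1L), c(-1L, rep(0L, n)),
             c(1L, rep(0L, n)), rep(1L, n + 1L))
  for (i in seq_len(n)) {
    for (s in c(-1L, 1L)) {
      d <- rep(0L, n + 1L)
      d[i + 1L] <- s
      ev[[length(ev) + 1L]] <- d
    }
  }
  m <- do.call(rbind, ev)
  ord <- do.call(order, as.data.frame(m))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- apply(m, 1L, paste, collapse = ",")
  m
}

is_allowed_event <- function(delta) {
  n <- length(delta) - 1L
  if (all(delta == 0L) || any(abs(delta) > 1L)) return(FALSE)
  dp <- delta[1L]
  dg <- delta[-1L]
  if (dp == 0L) return(sum(dg != 0L) == 1L)           # single gene +-1
  all(dg == 0L) || all(dg == dp)                      # pure ploidy or concerted
}

#' Enumerate allowed transitions from a state
#'
#' Lists every successor state reachable by one allowed event, respecting the
#' bounds ploidy `>= 1`, genes `>= 0`, and all counts `<= max_copy`. The list
#' is ordered lexicographically by event delta, so downstream tie-breaking is
#' deterministic.
#'
#' @param state Integer pattern `(p, g1, ..., gn)`.
#' @param panel A [probe_panel()] (supplies `max_copy`).
#' @return List with components `states` (matrix of successor patterns) and
#'   `events` (matrix of the corresponding deltas).
#' @export
allowed_transitions <- function(state, panel) {
  ev <- event_types(length(state) - 1L)
  succ <- sweep(ev, 2L, as.integer(state), `+`)
  ok <- succ[, 1L] >= 1L & apply(succ >= 0L, 1L, all) &
    apply(succ <= panel$max_copy, 1L, all)
  list(states = succ[ok, , drop = FALSE], events = ev[ok, , drop = FALSE])
}

#' Event of a parent-to-child edge
#'
#' @param parent,child Integer patterns of equal length.
#' @return The delta vector `child - parent` if it is an allowed event,
#'   otherwise `NULL`.
#' @export
event_of_edge <- function(parent, child) {
  stopifnot(length(parent) == length(child))
  delta <- as.integer(child) - as.integer(parent)
  if (is_allowed_event(delta)) delta else NULL
}

#' Decompose an arbitrary copy-number change into allowed events
#'
#' Inferred trees over several probes can carry edges whose raw delta is not
#' a single allowed event. Such an edge is reinterpreted as a sequence of
#' allowed events: if the ploidy changes by one but the genes move
#' inconsistently, the change is read as a concerted ploidy event in the
#' ploidy's direction followed by the minimal single-gene corrections (for
#' example, the raw change `(1, 1, 0)` becomes `(1, 1, 1)` then `(0, 0, -1)`).
#' Edges whose ploidy changes by two or more are ignored.
#'
#' @param parent,child Integer patterns of equal length.
#' @return List of event delta vectors, or `NULL` if the edge is ignored
#'   (ploidy mismatch of magnitude `>= 2`).
#' @export
decompose_edge <- function(parent, child) {
  stopifnot(length(parent) == length(child))
  delta <- as.integer(child) - as.integer(parent)
  dp <- delta[1L]
  if (abs(dp) >= 2L) return(NULL)
  if (is_allowed_event(delta)) return(list(delta))
  n <- length(delta) - 1L
  out <- list()
  rest <- delta
  if (dp != 0L) {
    conc <- rep(dp, n + 1L)
    out[[1L]] <- conc
    rest <- delta - conc
  }
  # minimal single-gene corrections, unit steps, gene order then sign
  for (i in seq_len(n)) {
    d <- rest[i + 1L]
    if (d != 0L) {
      step <- rep(0L, n + 1L)
      step[i + 1L] <- sign(d)
      for (k in seq_len(abs(d))) out[[length(out) + 1L]] <- step
    }
  }
  out
}

#' Uniform event-type frequencies
#'
#' @param n_genes Number of gene probes.
#' @return Named numeric vector: a uniform probability distribution over the
#'   allowed event types (names are event keys).
#' @export
uniform_frequencies <- function(n_genes) {
  ev <- event_types(n_genes)
  k <- nrow(ev)
  stats::setNames(rep(1 / k, k), rownames(ev))
}

# floor + renormalize; keeps -log p finite for every allowed type
apply_floor <- function(freqs, floor = 1e-6) {
  freqs[freqs < floor] <- floor
  freqs / sum(freqs)
}

check_frequencies <- function(freqs, n_genes) {
  ev <- event_types(n_genes)
  if (!all(rownames(ev) %in% names(freqs))) {
    stop("frequencies must cover every allowed event type")
  }
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must be a probability distribution")
  }
  invisible(TRUE)
}

# tally -> floored normalized distribution over all allowed types
normalize_tally <- function(tally, n_genes, floor = 1e-6) {
  ev <- event_types(n_genes)
  out <- stats::setNames(rep(0, nrow(ev)), rownames(ev))
  common <- intersect(names(tally), names(out))
  out[common] <- tally[common]
  if (sum(out) <= 0) return(uniform_frequencies(n_genes))
  apply_floor(out / sum(out), floor)
}

#' Weight of an event under a frequency distribution
#'
#' Edge weights are `-log p`: low-probability events are expensive, so
#' minimum-weight structures are maximum-likelihood ones.
#'
#' @param event Delta vector or event key.
#' @param freqs Named frequency vector (see [uniform_frequencies()]).
#' @return Nonnegative numeric weight `-log p(event)`.
#' @export
event_weight <- function(event, freqs) {
  key <- if (is.character(event)) event else paste(event, collapse = ",")
  p <- freqs[key]
  if (any(is.na(p))) stop("unknown event type: ", paste(key[is.na(p)], collapse = ", "))
  unname(-log(p))
}

#' Read or write event frequencies as two-column TSV
#'
#' The format is one row per event type: the delta vector as a comma string
#' and its probability, tab separated, with a header.
#'
#' @param freqs Named frequency vector.
#' @param path File path.
#' @return `read_frequencies()` returns the named vector; `write_frequencies()`
#'   returns `path` invisibly.
#' @export
write_frequencies <- function(freqs, path) {
  writeLines(c("event\tprobability",
               paste(names(freqs), format(freqs, digits = 12), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$probability), tab$event)
}
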