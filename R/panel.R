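#' Define a FISH probe panel
#'
#' A probe panel names the single ploidy probe (typically a centromeric probe
#' on a chromosome rarely altered in the tumor type, used as a proxy for
#' whole-cell ploidy) and an ordered set of gene probes, together with the
#' maximum copy number that is modeled. Copy numbers are modeled exactly,
#' from 0 up to `max_copy` (9 by default).
#'
#' @param ploidy Name of the ploidy probe (first column of data files).
#' @param genes Character vector of gene probe names, in file column order.
#' @param max_copy Largest copy number modeled per probe (integer `>= 2`).
#' @return An object of class `"probe_panel"`.
#' @examples
#' probe_panel("cep", c("LAMP3", "PROX1"))
#' @export
probe_panel <- function(ploidy, genes, max_copy = 9L) {
  stopifnot(is.character(ploidy), length(ploidy) == 1L, nzchar(ploidy))
  stopifnot(is.character(genes), length(genes) >= 1L, all(nzchar(genes)))
  nm <- c(ploidy, genes)
  if (anyDuplicated(nm)) stop("probe names must be unique")
  max_copy <- as.integer(max_copy)
  if (is.na(max_copy) || max_copy < 2L) stop("max_copy must be an integer >= 2")
  structure(
    list(ploidy = ploidy, genes = genes, max_copy = max_copy),
    class = "probe_panel"
  )
}

#' @export
print.probe_panel <- function(x, ...) {
  cat("Probe panel: ploidy probe '", x$ploidy, "', ",
      length(x$genes), " gene probe(s): ",
      paste(x$genes, collapse = ", "),
      "; copy numbers 0..", x$max_copy, "\n", sep = "")
  invisible(x)
}

n_genes <- function(panel) length(panel$genes)

probe_names <- function(panel) c(panel$ploidy, panel$genes)

#' All-2 (wild-type) pattern of a panel
#'
#' The diploid wild-type state, two copies of every probe. It is the root of
#' every progression tree.
#'
#' @param panel A [probe_panel()].
#' @return Integer vector of length `n + 1` (ploidy first), all equal to 2.
#' @export
root_pattern <- function(panel) {
  rep(2L, n_genes(panel) + 1L)
}

# "p,g1,...,gn" keys used to index patterns everywhere
pattern_key <- function(x) {
  if (is.matrix(x)) unname(apply(x, 1L, paste, collapse = ","))
  else paste(unname(x), collapse = ",")
}

key_to_pattern <- function(key) {
  as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

keys_to_matrix <- function(keys) {
  if (length(keys) == 0L) return(matrix(integer(), 0L, 0L))
  do.call(rbind, lapply(keys, key_to_pattern))
}

check_pattern_bounds <- function(pat, panel, allow_zero_ploidy = FALSE) {
  if (length(pat) != n_genes(panel) + 1L) {
    stop("pattern length ", length(pat), " does not match panel (",
         n_genes(panel) + 1L, " probes)")
  }
  lo_p <- if (allow_zero_ploidy) 0L else 1L
  if (pat[1L] < lo_p || any(pat < 0L) || any(pat > panel$max_copy)) {
    stop("pattern (", paste(pat, collapse = ","), ") outside bounds: ploidy >= ",
         lo_p, ", genes >= 0, all <= ", panel$max_copy)
  }
  invisible(TRUE)
}
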