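#' Construct a single-cell FISH dataset
#'
#' A dataset maps distinct cell-count patterns (configurations) to the number
#' of cells in which each pattern was observed. Patterns are integer vectors
#' `(p, g1, ..., gn)`: the ploidy-probe count first, then one count per gene
#' probe in panel order.
#'
#' @param patterns Integer matrix, one row per distinct pattern, `n + 1`
#'   columns (ploidy first); or a data.frame coercible to such a matrix.
#' @param counts Positive integer vector of cell counts, one per row.
#' @param panel A [probe_panel()].
#' @param sample_id,patient_id,stage Optional text labels carried through to
#'   outputs (e.g. which member of a paired design this sample is).
#' @param allow_zero_ploidy Permit patterns with a ploidy-probe count of 0.
#'   By default such cells are rejected as input errors: a transition below
#'   one ploidy copy is biologically meaningless.
#' @return An object of class `"fish_data"`.
#' @seealso [read_fish_data()], [marginalize()]
#' @export
fish_data <- function(patterns, counts, panel, sample_id = "", patient_id = "",
                      stage = "", allow_zero_ploidy = FALSE) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  counts <- as.integer(counts)
  if (nrow(patterns) == 0L) stop("empty dataset: no cell count patterns")
  if (length(counts) != nrow(patterns)) stop("one count per pattern required")
  if (any(is.na(patterns)) || any(is.na(counts))) stop("NA in patterns or counts")
  if (any(counts < 1L)) stop("all cell counts must be >= 1")
  if (ncol(patterns) != n_genes(panel) + 1L) {
    stop("patterns have ", ncol(patterns), " columns; panel expects ",
         n_genes(panel) + 1L)
  }
  apply(patterns, 1L, check_pattern_bounds, panel = panel,
        allow_zero_ploidy = allow_zero_ploidy)
  # aggregate duplicated patterns
  keys <- pattern_key(patterns)
  if (anyDuplicated(keys)) {
    agg <- rowsum(counts, keys)
    keys <- rownames(agg)
    counts <- as.integer(agg[, 1L])
    patterns <- keys_to_matrix(keys)
  }
  ord <- order(keys)  # deterministic storage order
  patterns <- patterns[ord, , drop = FALSE]
  counts <- counts[ord]
  keys <- keys[ord]
  dimnames(patterns) <- list(keys, probe_names(panel))
  structure(
    list(patterns = patterns, counts = counts, panel = panel,
         sample_id = sample_id, patient_id = patient_id, stage = stage),
    class = "fish_data"
  )
}

#' @export
print.fish_data <- function(x, ...) {
  cat("FISH dataset", if (nzchar(x$sample_id)) paste0(" '", x$sample_id, "'"),
      ": ", nrow(x$patterns), " distinct pattern(s), ",
      sum(x$counts), " cells over ", ncol(x$patterns), " probes (",
      paste(colnames(x$patterns), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fish_data <- function(x, ...) {
  df <- as.data.frame(x$patterns, row.names = FALSE)
  df$count <- x$counts
  df
}

total_cells <- function(ds) sum(ds$counts)

#' Read a tab-delimited single-cell FISH count file
#'
#' Two dialects are accepted and auto-detected from the header row. In the
#' per-cell dialect every body row is one cell's pattern and identical rows
#' are aggregated. In the pattern+count dialect a trailing column named
#' `count` holds the number of cells per pattern.
#'
#' @param path Path to a UTF-8 tab-delimited text file. The header row names
#'   the probes, ploidy probe first.
#' @param panel Optional [probe_panel()]; when `NULL`, a panel is built from
#'   the header (first column = ploidy probe, `max_copy = 9`). When supplied,
#'   header names must match the panel.
#' @param allow_zero_ploidy Accept ploidy-probe counts of 0 (default: error).
#' @param clamp Clamp counts above `max_copy` down to `max_copy` instead of
#'   rejecting them.
#' @inheritParams fish_data
#' @return A [fish_data()] object.
#' @export
read_fish_data <- function(path, panel = NULL, sample_id = "", patient_id = "",
                           stage = "", allow_zero_ploidy = FALSE,
                           clamp = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  has_count <- tolower(header[length(header)]) == "count"
  probes <- if (has_count) header[-length(header)] else header
  if (length(probes) < 2L) stop("header must name a ploidy probe and >= 1 gene probe")
  if (is.null(panel)) {
    panel <- probe_panel(probes[1L], probes[-1L])
  } else if (!identical(probes, probe_names(panel))) {
    stop("header (", paste(probes, collapse = ", "),
         ") does not match panel (", paste(probe_names(panel), collapse = ", "), ")")
  }
  body <- lines[-1L]
  if (length(body) == 0L) stop("empty dataset: file '", path, "' has no body rows")
  ncol_expected <- length(header)
  rows <- lapply(seq_along(body), function(i) {
    fields <- trimws(strsplit(body[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != ncol_expected) {
      stop("parse error at line ", i + 1L, ": expected ", ncol_expected,
           " fields, found ", length(fields))
    }
    vals <- suppressWarnings(as.integer(fields))
    if (any(is.na(vals))) {
      stop("parse error at line ", i + 1L, ": non-integer value")
    }
    vals
  })
  tab <- do.call(rbind, rows)
  if (has_count) {
    counts <- tab[, ncol_expected]
    if (any(counts < 1L)) stop("count column must be >= 1")
    patterns <- tab[, -ncol_expected, drop = FALSE]
  } else {
    counts <- rep(1L, nrow(tab))
    patterns <- tab
  }
  if (clamp) patterns[patterns > panel$max_copy] <- panel$max_copy
  bad <- which(patterns > panel$max_copy | patterns < 0L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("range error at line ", bad[1L, 1L] + 1L, ": count outside [0, ",
         panel$max_copy, "]")
  }
  fish_data(patterns, counts, panel, sample_id = sample_id,
            patient_id = patient_id, stage = stage,
            allow_zero_ploidy = allow_zero_ploidy)
}

#' Write a dataset as a tab-delimited pattern+count file
#'
#' @param ds A [fish_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fish_data <- function(ds, path) {
  header <- paste(c(colnames(ds$patterns), "count"), collapse = "\t")
  body <- paste(apply(ds$patterns, 1L, paste, collapse = "\t"),
                ds$counts, sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Marginalize a dataset onto a probe subset
#'
#' Restricts the dataset to a subset of probes (which must include the ploidy
#' probe) by summing the cell counts of patterns that agree on the kept
#' dimensions. The total cell count is conserved.
#'
#' @param ds A [fish_data()] object.
#' @param probes Character vector of probe names to keep; must contain the
#'   ploidy probe.
#' @return A [fish_data()] over the reduced panel.
#' @examples
#' pan <- probe_panel("cep", c("g1", "g2"))
#' ds <- fish_data(rbind(c(2, 2, 3), c(2, 4, 3)), c(5, 7), pan)
#' marginalize(ds, c("cep", "g2"))
#' @export
marginalize <- function(ds, probes) {
  stopifnot(inherits(ds, "fish_data"))
  panel <- ds$panel
  if (length(probes) == 0L || !(panel$ploidy %in% probes)) {
    stop("probe subset must be nonempty and contain the ploidy probe '",
         panel$ploidy, "'")
  }
  unknown <- setdiff(probes, probe_names(panel))
  if (length(unknown) > 0L) stop("unknown probe(s): ", paste(unknown, collapse = ", "))
  keep_genes <- panel$genes[panel$genes %in% probes]
  cols <- c(panel$ploidy, keep_genes)
  sub <- ds$patterns[, cols, drop = FALSE]
  new_panel <- probe_panel(panel$ploidy, keep_genes, panel$max_copy)
  fish_data(sub, ds$counts, new_panel, sample_id = ds$sample_id,
            patient_id = ds$patient_id, stage = ds$stage,
            allow_zero_ploidy = min(ds$patterns[, 1L]) == 0L)
}
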