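# MILP backend: the merge program is solved exactly with HiGHS
# branch-and-bound through scipy.optimize.milp, driven by the bundled
# worker script inst/python/milp_worker.py. Instances are batched into a
# single interpreter invocation so that study-scale runs (hundreds of
# merges) pay the startup cost once.

the_backend <- new.env(parent = emptyenv())

find_python <- function(python = NULL) {
  if (!is.null(python)) return(python)
  if (!is.null(the_backend$python)) return(the_backend$python)
  opt <- getOption("ploidytree.python", Sys.getenv("PLOIDYTREE_PYTHON", ""))
  cand <- c(opt, Sys.which("python3"), Sys.which("python"))
  cand <- cand[nzchar(cand)]
  for (p in cand) {
    ok <- tryCatch(
      system2(p, c("-c", shQuote("import scipy.optimize")),
              stdout = FALSE, stderr = FALSE) == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (isTRUE(ok)) {
      the_backend$python <- p
      return(p)
    }
  }
  stop("no python interpreter with scipy found; install scipy or set ",
       "options(ploidytree.python=...)")
}

worker_script <- function() {
  path <- system.file("python", "milp_worker.py", package = "ploidytree")
  if (!nzchar(path)) stop("internal error: MILP worker script not installed")
  path
}

# problems: list of merge_problem objects -> list of raw backend solutions
milp_solve_batch <- function(problems, control = ploidytree_control()) {
  py <- find_python(control$python)
  instances <- lapply(problems, function(pr) {
    list(m = pr$m, n = pr$n,
         parentA = ifelse(is.na(pr$parentA), 0L, pr$parentA),
         parentB = ifelse(is.na(pr$parentB), 0L, pr$parentB),
         wA = pr$wA, wB = pr$wB,
         p = pr$p,            # m x n matrix -> nested rows
         mismatch = pr$mismatch * 1L,
         rho = pr$rho, sigma = pr$sigma, tau = pr$tau,
         time_limit = control$timeout)
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(instances, fin, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  # HiGHS writes progress chatter to stdout; capture it away from the console
  flog <- tempfile(fileext = ".log")
  on.exit(unlink(flog), add = TRUE)
  status <- system2(py, c(worker_script(), fin, fout),
                    stdout = flog, stderr = flog)
  if (status != 0L || !file.exists(fout)) {
    stop("MILP backend failed (exit status ", status, ")")
  }
  out <- jsonlite::fromJSON(fout, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  lapply(out, function(s) {
    if (identical(s$status, "failed")) {
      stop("MILP solver reported failure: ", s$message,
           " (the merge program is always feasible; this is an internal error)")
    }
    s
  })
}

# robust row-major coercion of a backend matrix field
backend_matrix <- function(x, m, n) {
  if (is.matrix(x) && identical(dim(x), c(m, n))) {
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.numeric(unlist(x)), m, n, byrow = TRUE)
}
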