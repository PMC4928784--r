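#' Control parameters for tree fitting and merging
#'
#' Collects the tunable parameters of the pipeline in one list.
#'
#' EM settings (single-gene trees): `eps` is the per-node probability that a
#' branching parent is randomly resampled between iterations; `tol` is the
#' L-infinity convergence threshold on event frequencies; `max_iter` caps EM
#' iterations; `restarts` is the number of independent EM restarts (the best
#' branching across restarts is kept); `floor` is the probability floor
#' applied after every frequency update so `-log p` stays finite.
#'
#' MILP settings (tree merging): `rho` penalizes merged nodes whose two
#' single-gene ploidies disagree, `sigma` penalizes mismatch between observed
#' and model node frequencies, `tau` penalizes leaving an observed joint
#' state out of the merged tree; `timeout` is the per-merge solver time limit
#' in seconds. `python` optionally names the python interpreter used for the
#' MILP backend (default: found on the PATH).
#'
#' @param eps,tol,max_iter,restarts,floor EM settings, see Details.
#' @param rho,sigma,tau,timeout MILP settings, see Details.
#' @param python Optional path to a python3 with scipy.
#' @return A list of class `"ploidytree_control"`.
#' @export
ploidytree_control <- function(eps = 0.05, tol = 1e-6, max_iter = 200L,
                               restarts = 5L, floor = 1e-6,
                               rho = 1000, sigma = 100, tau = 100,
                               timeout = 300, python = NULL) {
  stopifnot(eps >= 0, eps <= 1, tol > 0, max_iter >= 1L, restarts >= 1L,
            floor > 0, floor < 1, rho >= 0, sigma >= 0, tau >= 0, timeout > 0)
  structure(list(eps = eps, tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), floor = floor,
                 rho = rho, sigma = sigma, tau = tau, timeout = timeout,
                 python = python),
            class = "ploidytree_control")
}
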