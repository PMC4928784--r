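#!/usr/bin/env python3
"""Batch MILP worker for ploidytree tree merging.

Reads a JSON list of merge instances from argv[1], solves each with
scipy.optimize.milp (HiGHS, exact branch-and-bound), and writes a JSON list
of solutions to argv[2].

Instance fields (indices 1-based, as sent from R):
  m, n            node counts of trees A and B (root has index 1)
  parentA, parentB  parent index per node (0 for the root)
  wA, wB          weight of the edge into each node (root weight 0)
  p               m x n observed joint frequency matrix (nested rows)
  mismatch        m x n 0/1 matrix: ploidy of A-node i != ploidy of B-node j
  rho, sigma, tau penalties; time_limit seconds

Variables per pair (i, j): a, b, c binary edge indicators (edge derived from
tree A, tree B, or both), q continuous node frequency, t continuous auxiliary
variable linearizing |p - q|. Layout: [a, b, c, q, t], each m*n long,
pair index i*n + j (0-based).
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, Bounds, milp


def solve_instance(inst):
    m = int(inst["m"])
    n = int(inst["n"])
    parentA = np.atleast_1d(np.asarray(inst["parentA"], dtype=int)) - 1  # -1 => root
    parentB = np.atleast_1d(np.asarray(inst["parentB"], dtype=int)) - 1
    wA = np.atleast_1d(np.asarray(inst["wA"], dtype=float))
    wB = np.atleast_1d(np.asarray(inst["wB"], dtype=float))
    p = np.asarray(inst["p"], dtype=float).reshape(m, n)
    mism = np.asarray(inst["mismatch"], dtype=float).reshape(m, n)
    rho = float(inst["rho"])
    sigma = float(inst["sigma"])
    tau = float(inst["tau"])

    mn = m * n
    nvar = 5 * mn
    A_off, B_off, C_off, Q_off, T_off = 0, mn, 2 * mn, 3 * mn, 4 * mn

    def pidx(i, j):
        return i * n + j

    lb = np.zeros(nvar)
    ub = np.ones(nvar)
    ub[T_off:T_off + mn] = np.inf
    # fixed variables: no A-edge into the A-root's row, no B-edge into the
    # B-root's column, c only off the root row/column, c_11 = 1
    for j in range(n):
        ub[A_off + pidx(0, j)] = 0.0
        if j != 0:
            ub[C_off + pidx(0, j)] = 0.0
    for i in range(m):
        ub[B_off + pidx(i, 0)] = 0.0
        if i != 0:
            ub[C_off + pidx(i, 0)] = 0.0
    ub[A_off + pidx(0, 0)] = 0.0
    ub[B_off + pidx(0, 0)] = 0.0
    lb[C_off + pidx(0, 0)] = 1.0
    ub[C_off + pidx(0, 0)] = 1.0

    rows, cols, vals = [], [], []
    con_lb, con_ub = [], []
    nrow = 0

    def add(entries, lo, hi):
        nonlocal nrow
        for c, v in entries:
            rows.append(nrow)
            cols.append(c)
            vals.append(v)
        con_lb.append(lo)
        con_ub.append(hi)
        nrow += 1

    sel = lambda i, j: [(A_off + pidx(i, j), 1.0), (B_off + pidx(i, j), 1.0),
                        (C_off + pidx(i, j), 1.0)]

    for i in range(m):
        for j in range(n):
            k = parentA[i]
            l = parentB[j]
            # at most one parent
            add(sel(i, j), -np.inf, 1.0)
            # a joint edge must have a parent
            if i != 0:
                add([(A_off + pidx(i, j), 1.0)] +
                    [(c, -v) for c, v in sel(k, j)], -np.inf, 0.0)
            if j != 0:
                add([(B_off + pidx(i, j), 1.0)] +
                    [(c, -v) for c, v in sel(i, l)], -np.inf, 0.0)
            if i != 0 and j != 0:
                add([(C_off + pidx(i, j), 1.0)] +
                    [(c, -v) for c, v in sel(k, l)], -np.inf, 0.0)
            # only nodes in the merged tree have nonzero frequency
            add([(Q_off + pidx(i, j), 1.0)] +
                [(c, -v) for c, v in sel(i, j)], -np.inf, 0.0)
            # |p - q| linearization
            add([(T_off + pidx(i, j), 1.0), (Q_off + pidx(i, j), 1.0)],
                p[i, j], np.inf)
            add([(T_off + pidx(i, j), 1.0), (Q_off + pidx(i, j), -1.0)],
                -p[i, j], np.inf)
    # marginal sums match the observations
    for i in range(m):
        add([(Q_off + pidx(i, j), 1.0) for j in range(n)],
            p[i, :].sum(), p[i, :].sum())
    for j in range(n):
        add([(Q_off + pidx(i, j), 1.0) for i in range(m)],
            p[:, j].sum(), p[:, j].sum())
    # all edges of trees A and B are used
    for i in range(1, m):
        add([(A_off + pidx(i, j), 1.0) for j in range(n)] +
            [(C_off + pidx(i, j), 1.0) for j in range(n)], 1.0, np.inf)
    for j in range(1, n):
        add([(B_off + pidx(i, j), 1.0) for i in range(m)] +
            [(C_off + pidx(i, j), 1.0) for i in range(m)], 1.0, np.inf)

    A = sparse.csc_matrix((vals, (rows, cols)), shape=(nrow, nvar))

    obs = (p > 0).astype(float)
    cost = np.zeros(nvar)
    for i in range(m):
        for j in range(n):
            k = pidx(i, j)
            node_pen = rho * mism[i, j] - tau * obs[i, j]
            cost[A_off + k] = wA[i] + node_pen
            cost[B_off + k] = wB[j] + node_pen
            cost[C_off + k] = wA[i] + wB[j] + node_pen
            cost[T_off + k] = sigma
    const = tau * obs.sum()
    # infinitesimal preference for non-root c edges when solving: a c edge
    # and an a+b pair carry identical weight, and the tie is broken toward
    # the joint (concerted) interpretation; the reported objective uses the
    # unperturbed cost
    cost_solve = cost.copy()
    cost_solve[C_off:C_off + mn] -= 1e-7
    cost_solve[C_off + pidx(0, 0)] = cost[C_off + pidx(0, 0)]

    integrality = np.zeros(nvar)
    integrality[:3 * mn] = 1

    res = milp(c=cost_solve,
               constraints=LinearConstraint(A, np.array(con_lb), np.array(con_ub)),
               integrality=integrality,
               bounds=Bounds(lb, ub),
               options={"mip_rel_gap": 0.0,
                        "time_limit": float(inst.get("time_limit", 300.0)),
                        "presolve": True})

    if res.x is None:
        return {"status": "failed", "message": str(res.message)}
    x = res.x
    a = np.round(x[A_off:A_off + mn]).reshape(m, n)
    b = np.round(x[B_off:B_off + mn]).reshape(m, n)
    c = np.round(x[C_off:C_off + mn]).reshape(m, n)
    q = x[Q_off:Q_off + mn].reshape(m, n)
    status = "optimal" if res.status == 0 else "feasible"
    return {
        "status": status,
        "objective": float(cost @ x + const),
        "a": a.astype(int).tolist(),
        "b": b.astype(int).tolist(),
        "c": c.astype(int).tolist(),
        "q": q.tolist(),
    }


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [solve_instance(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
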