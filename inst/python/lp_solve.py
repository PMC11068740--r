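"""Batch LP/MILP solving via scipy (HiGHS).

Reads a JSON list of problems, writes a JSON list of results.  Serves as an
independent backend for cross-checking the package's built-in simplex.

Usage: python lp_solve.py <in.json> <out.json>
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog, milp, LinearConstraint, Bounds


def solve_one(p):
    c = np.asarray(p["c"], dtype=float)
    mx = p["sense"] == "max"
    obj = -c if mx else c
    A = np.asarray(p["A"], dtype=float) if p["A"] else np.zeros((0, c.size))
    rs = list(p["row_sense"])
    rhs = np.asarray(p["rhs"], dtype=float)
    lbv = np.asarray(p["lb"], dtype=float)
    ubv = np.asarray(p["ub"], dtype=float)
    cl = rhs.copy()
    cu = rhs.copy()
    for i, s in enumerate(rs):
        if s == "L":
            cl[i] = -np.inf
        elif s == "G":
            cu[i] = np.inf
    ints = [int(i) for i in p.get("integers", [])]
    if ints:
        integrality = np.zeros(c.size)
        integrality[ints] = 1
        cons = [LinearConstraint(A, cl, cu)] if A.shape[0] else []
        res = milp(obj, constraints=cons, bounds=Bounds(lbv, ubv),
                   integrality=integrality,
                   options={"mip_rel_gap": 0.0})
        if res.status != 0:
            status = {2: "infeasible", 3: "unbounded"}.get(res.status, "error")
            return {"status": status}
        return {"status": "optimal",
                "obj": (-res.fun if mx else res.fun),
                "x": list(res.x)}
    A_ub, b_ub, A_eq, b_eq = [], [], [], []
    for i, s in enumerate(rs):
        if s == "E":
            A_eq.append(A[i]); b_eq.append(rhs[i])
        elif s == "L":
            A_ub.append(A[i]); b_ub.append(rhs[i])
        else:
            A_ub.append(-A[i]); b_ub.append(-rhs[i])
    res = linprog(obj,
                  A_ub=np.asarray(A_ub) if A_ub else None,
                  b_ub=np.asarray(b_ub) if b_ub else None,
                  A_eq=np.asarray(A_eq) if A_eq else None,
                  b_eq=np.asarray(b_eq) if b_eq else None,
                  bounds=list(zip(lbv, ubv)), method="highs")
    if res.status == 2:
        return {"status": "infeasible"}
    if res.status == 3:
        return {"status": "unbounded"}
    if res.status != 0:
        return {"status": "error"}
    return {"status": "optimal",
            "obj": (-res.fun if mx else res.fun),
            "x": list(res.x)}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = [solve_one(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
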