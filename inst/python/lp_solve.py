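"""Generic sparse linear-program solver bridge.

Reads a JSON problem description, solves one LP per objective vector with
scipy's HiGHS backend (constraints are shared across objectives), and writes
the solutions back as JSON.  Usage:

    python lp_solve.py problem.json solutions.json

Input schema (all indices 0-based):
    ncol        number of variables (all bounded to [0, inf))
    A_eq        {"i": [...], "j": [...], "v": [...]} sparse triplets
    b_eq        [...]
    A_ub, b_ub  optional, same layout; may be absent/null
    objectives  list of dense cost vectors, each of length ncol
    options     optional dict passed to linprog(options=...)

Output schema:
    {"solutions": [{"status": int, "message": str,
                    "objective": float, "x": [...]}, ...]}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog


def _coo(d, nrow, ncol):
    if d is None:
        return None
    return sparse.coo_matrix(
        (np.asarray(d["v"], dtype=float),
         (np.asarray(d["i"], dtype=int), np.asarray(d["j"], dtype=int))),
        shape=(nrow, ncol)).tocsc()


def main(path_in, path_out):
    with open(path_in) as fh:
        prob = json.load(fh)

    ncol = int(prob["ncol"])
    b_eq = np.asarray(prob["b_eq"], dtype=float)
    A_eq = _coo(prob["A_eq"], b_eq.size, ncol)
    b_ub = prob.get("b_ub")
    A_ub = None
    if b_ub is not None:
        b_ub = np.asarray(b_ub, dtype=float)
        A_ub = _coo(prob.get("A_ub"), b_ub.size, ncol)
    options = prob.get("options") or {}

    out = []
    for c in prob["objectives"]:
        res = linprog(np.asarray(c, dtype=float),
                      A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                      bounds=(0, None), method="highs", options=options)
        out.append({
            "status": int(res.status),
            "message": str(res.message),
            "objective": float(res.fun) if res.status == 0 else None,
            "x": res.x.tolist() if res.status == 0 else None,
        })

    with open(path_out, "w") as fh:
        json.dump({"solutions": out}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
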