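"""Generic mixed-integer linear program solve via scipy's HiGHS interface.

Reads a JSON model from argv[1] and writes a JSON result to argv[2].

Model JSON:
  n          -- number of variables
  obj        -- objective coefficients (minimize)
  lb, ub     -- variable bounds (null -> +/- inf)
  integrality-- 0 continuous / 1 integer, per variable
  a_row, a_col, a_val -- sparse constraint matrix triplets (1-based indices)
  n_rows     -- number of constraint rows
  row_lb, row_ub -- constraint bounds (null -> +/- inf)
  time_limit -- seconds

Result JSON: status (optimal|timeout|infeasible|unbounded|error),
  objective, x (when a solution is available).
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, Bounds, milp


def main(model_path, out_path):
    with open(model_path) as fh:
        m = json.load(fh)

    n = int(m["n"])
    obj = np.asarray(m["obj"], dtype=float)

    def arr(key, default, size):
        vals = m.get(key)
        if vals is None:
            return np.full(size, default)
        if isinstance(vals, (int, float)):
            vals = [vals]
        return np.array([default if v is None else v for v in vals],
                        dtype=float)

    lb = arr("lb", -np.inf, n)
    ub = arr("ub", np.inf, n)
    integrality = np.asarray(m["integrality"], dtype=int)

    n_rows = int(m["n_rows"])
    row = np.asarray(m.get("a_row", []), dtype=int) - 1
    col = np.asarray(m.get("a_col", []), dtype=int) - 1
    val = np.asarray(m.get("a_val", []), dtype=float)
    A = sparse.csc_matrix((val, (row, col)), shape=(n_rows, n))
    row_lb = arr("row_lb", -np.inf, n_rows)
    row_ub = arr("row_ub", np.inf, n_rows)

    res = milp(
        c=obj,
        constraints=LinearConstraint(A, row_lb, row_ub) if n_rows else (),
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options={"time_limit": float(m.get("time_limit") or 600),
                 "presolve": True},
    )

    status_map = {0: "optimal", 1: "timeout", 2: "infeasible",
                  3: "unbounded"}
    out = {"status": status_map.get(res.status, "error"),
           "message": res.message}
    if res.x is not None:
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
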