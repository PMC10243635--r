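"""3D Voronoi vertex graph of a seed-point cloud.

Reads seed points (one "x y z" row per line) from argv[1], computes their
Delaunay tetrahedralization (qhull) and emits the finite Voronoi 1-skeleton:
Voronoi vertices are the circumcenters of the tetrahedra, and two vertices
are joined iff their tetrahedra share a triangular face (the dual of a
finite Voronoi ridge segment). Writes vertex coordinates (CSV x,y,z) to
argv[2] and the edge list (TSV, 0-based ids) to argv[3].
"""
import sys

import numpy as np
from scipy.spatial import Delaunay


def main() -> int:
    pts = np.loadtxt(sys.argv[1], ndmin=2)
    if pts.shape[0] < 5 or pts.shape[1] != 3:
        print("need at least 5 seed points in 3D", file=sys.stderr)
        return 2
    try:
        tri = Delaunay(pts)
    except Exception as exc:  # qhull failure on degenerate input
        print(f"Delaunay tessellation failed: {exc}", file=sys.stderr)
        return 2
    simp = tri.simplices
    if simp.shape[1] != 4:
        print("degenerate (non-3D) tessellation", file=sys.stderr)
        return 2
    s = pts[simp]
    a = s[:, 0, :]
    b = s[:, 1:, :] - a[:, None, :]
    rhs = 0.5 * np.sum(b * b, axis=2)
    with np.errstate(all="ignore"):
        try:
            cc = a + np.linalg.solve(b, rhs[..., None])[..., 0]
        except np.linalg.LinAlgError:
            print("singular simplex geometry (coplanar seeds?)",
                  file=sys.stderr)
            return 2
    finite = np.all(np.isfinite(cc), axis=1)
    new_id = np.full(len(cc), -1, dtype=np.int64)
    new_id[finite] = np.arange(int(finite.sum()))
    nb = tri.neighbors
    ii, jj = np.nonzero(nb >= 0)
    e = np.stack([ii, nb[ii, jj]], axis=1)
    e = e[e[:, 0] < e[:, 1]]
    e = new_id[e]
    e = e[np.all(e >= 0, axis=1)]
    np.savetxt(sys.argv[2], cc[finite], fmt="%.17g", delimiter=",")
    np.savetxt(sys.argv[3], e, fmt="%d", delimiter="\t")
    return 0


if __name__ == "__main__":
    sys.exit(main())
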