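"""Batch UMAP embedding runner.

Reads a JSON job file: {"n_neighbors": int, "min_dist": float,
"seed": int, "inputs": [csv, ...], "outputs": [csv, ...]}.
Each input CSV is a numeric matrix (no header); the corresponding output
CSV receives the 2-D embedding. One process embeds all jobs so the numba
JIT cost is paid once.
"""
import json
import sys

import numpy as np


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    import umap  # deferred: slow import

    for src, dst in zip(job["inputs"], job["outputs"]):
        x = np.loadtxt(src, delimiter=",", ndmin=2)
        reducer = umap.UMAP(
            n_neighbors=int(job["n_neighbors"]),
            min_dist=float(job["min_dist"]),
            n_components=2,
            random_state=int(job["seed"]),
            n_jobs=1,
        )
        emb = reducer.fit_transform(x)
        np.savetxt(dst, emb, delimiter=",")


if __name__ == "__main__":
    main(sys.argv[1])
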