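"""Fit one UMAP model on a pooled feature matrix and write 2-D coordinates.

Usage: python umap_embed.py in.csv out.csv n_neighbors min_dist seed
"""
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")


def main(argv):
    in_csv, out_csv, n_neighbors, min_dist, seed = argv
    x = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    import umap  # deferred: slow import

    model = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        n_components=2,
        random_state=int(seed),
    )
    emb = model.fit_transform(x)
    np.savetxt(out_csv, emb, delimiter=",", fmt="%.10g")


if __name__ == "__main__":
    main(sys.argv[1:6])
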