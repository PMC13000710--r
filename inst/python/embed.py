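"""Run t-SNE or UMAP on a CSV matrix; used by specfuse::embed_and_score.

Usage: python embed.py <config.json>
The config names the input CSV (samples in rows, no header), the output
CSV for the 2-D coordinates, the method, its hyperparameters and the
random state.
"""
import json
import sys

import numpy as np


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    X = np.loadtxt(cfg["input"], delimiter=",", ndmin=2)
    if cfg["method"] == "tsne":
        from sklearn.manifold import TSNE

        emb = TSNE(
            n_components=2,
            perplexity=cfg["perplexity"],
            max_iter=cfg["n_iter"],
            init="random",
            random_state=cfg["seed"],
        ).fit_transform(X)
    elif cfg["method"] == "umap":
        from umap import UMAP

        emb = UMAP(
            n_components=2,
            n_neighbors=cfg["n_neighbors"],
            min_dist=cfg["min_dist"],
            random_state=cfg["seed"],
        ).fit_transform(X)
    else:
        raise ValueError("unknown method: %s" % cfg["method"])
    np.savetxt(cfg["out"], emb, delimiter=",")


if __name__ == "__main__":
    main(sys.argv[1])
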