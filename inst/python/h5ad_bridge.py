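"""Plain-text bridge between AnnData .h5ad containers and the R package.

export: .h5ad -> directory of CSVs (X.csv, spatial.csv, obs.csv, per-column
        category levels).
import: directory of CSVs -> .h5ad.
"""
import sys
import os

import numpy as np
import pandas as pd
import anndata as ad
from scipy import sparse


def do_export(path, outdir):
    a = ad.read_h5ad(path)
    X = a.X
    if sparse.issparse(X):
        X = X.toarray()
    X = np.asarray(X)
    pd.DataFrame(X, index=a.obs_names.astype(str),
                 columns=a.var_names.astype(str)).to_csv(
        os.path.join(outdir, "X.csv"))
    if "spatial" in a.obsm:
        sp = np.asarray(a.obsm["spatial"])[:, :2]
        pd.DataFrame(sp, index=a.obs_names.astype(str),
                     columns=["x", "y"]).to_csv(
            os.path.join(outdir, "spatial.csv"))
    obs = a.obs.copy()
    for col in obs.columns:
        levels = []
        if isinstance(obs[col].dtype, pd.CategoricalDtype):
            levels = [str(v) for v in obs[col].cat.categories]
            obs[col] = obs[col].astype(str)
        with open(os.path.join(outdir, f"levels_{col}.txt"), "w") as fh:
            fh.write("\n".join(levels) + ("\n" if levels else ""))
    obs.to_csv(os.path.join(outdir, "obs.csv"))


def do_import(indir, path):
    X = pd.read_csv(os.path.join(indir, "X.csv"), index_col=0)
    a = ad.AnnData(X=X.to_numpy(dtype=float),
                   obs=pd.DataFrame(index=X.index.astype(str)))
    a.var_names = X.columns.astype(str)
    sp = pd.read_csv(os.path.join(indir, "spatial.csv"), index_col=0)
    a.obsm["spatial"] = sp.loc[a.obs_names].to_numpy(dtype=float)
    lab_path = os.path.join(indir, "labels.csv")
    if os.path.exists(lab_path):
        lab = pd.read_csv(lab_path, index_col=0)
        with open(os.path.join(indir, "levels.txt")) as fh:
            levels = [l for l in fh.read().splitlines() if l]
        with open(os.path.join(indir, "labels_name.txt")) as fh:
            name = fh.read().strip() or "label"
        a.obs[name] = pd.Categorical(
            lab.iloc[:, 0].astype(str).loc[a.obs_names], categories=levels)
    a.write_h5ad(path)


if __name__ == "__main__":
    mode, src, dst = sys.argv[1], sys.argv[2], sys.argv[3]
    if mode == "export":
        do_export(src, dst)
    elif mode == "import":
        do_import(src, dst)
    else:
        raise SystemExit(f"unknown mode: {mode}")
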