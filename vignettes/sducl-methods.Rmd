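---
title: "Signal-diffusion contrastive embeddings for spatial transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-diffusion contrastive embeddings for spatial transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sducl)
```

## The problem and the model

A spatial transcriptomics slide gives, per spot, a gene expression vector, a
2-D position, and (often) a histology image patch. Spots belonging to one
spatial domain share an expression program *and* a neighbourhood: good
embeddings should therefore mix molecular similarity with spatial context.
`sducl` does this with three cooperating pieces.

**1. Feature augmentation.** The fused input is `F = E_g ⊕ E_i ⊕ E_s`
(column concatenation). `E_g` is standard expression preprocessing
(library-size normalization to the median depth, `log1p`, top-variance gene
selection, per-gene z-score). `E_i` summarizes the histology patch under
each spot. `E_s` encodes where a spot sits in the neighbour graph: the Katz
index matrix `K = Σ_{l≥1} β^l A^l` scores every spot pair by attenuated
path counts, and its rows are compressed to a fixed width `d_s` by
truncated SVD (row *i* of `U·diag(σ)` is spot *i*'s loading on the dominant
connectivity modes). Each block is z-standardized before fusion so no
modality dominates by scale — the paper-level question of how to balance
modalities has no canonical answer, and equal column variance is the
neutral choice.

**2. Diffusion microenvironments.** The contrastive context of spot *i* is
not the whole graph (as in Deep Graph Infomax) but the subnetwork a
biological signal starting at *i* would reach: `m_i = exp(−αL)·e_i`, the
graph heat kernel applied to a unit source. Because `L·1 = 0`, the kernel
is symmetric, entrywise nonnegative and doubly stochastic — diffusion
conserves signal mass, and row *i* of `exp(−αL)` *is* the diffused signal
from source *i*, so one eigendecomposition yields all N microenvironments.
Nodes are ranked by accumulated signal and the top `N_sub` form the
microenvironment; ranking ties resolve to the smaller index so results are
reproducible.

**3. Contrastive + reconstruction training.** A two-layer GCN encoder
(widths `d → 512 → 64`, ReLU) embeds both the original features and a
corrupted copy in which feature rows are randomly shuffled while topology
is untouched. The readout `S_i = σ(mean_{j∈env(i)} h_j)` squashes each
microenvironment mean into `(0,1)`; a bilinear discriminator
`D(h,s) = σ(hᵀWs)` is trained to accept `(h_i, S_i)` and reject
`(h′_i, S_i)`, plus the mirrored term with the corrupted branch's own
summaries, both as logit-stable binary cross-entropies. A mirrored GCN
decoder reconstructs `F` from `H` under a squared-error loss. The joint
objective is `L = α_rec L_rec + β_con (L_con + L_con′)`.

## Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `k` | 6 | neighbours per spot; matches the hexagonal packing of Visium spots |
| `alpha_diffusion` | 0.1 | diffusion rate (dimensionless time); small values keep microenvironments local |
| `n_sub` | 20 | microenvironment size; ≈ three rings of a k = 6 graph |
| `beta_katz` | 0.1 | Katz attenuation; auto-shrunk to `0.9/ρ(A)` if the series would diverge |
| `n_hvg` | 3000 | variable genes kept (all genes when fewer) |
| `d_i`, `d_s` | 50, 32 | image / topology feature widths (patchstats emits 30 image features) |
| `hidden`, `embed` | 512, 64 | encoder widths, common practice for GCN embedders |
| `epochs`, `lr`, `weight_decay` | 500, 1e-3, 1e-4 | full-batch Adam schedule |
| `alpha_rec`, `beta_con` | 1, 1 | loss weights; zeroing one gives the reconstruction-only / contrastive-only variants |

Model variants used in ablation-style comparisons are plain configurations:
`use_image = FALSE`, `use_katz = FALSE`, `use_fusion = FALSE` (expression
block only), `use_signal = FALSE` (microenvironments replaced by one
whole-graph summary, `n_sub = N` — the DGI readout), `alpha_rec = 0`,
`beta_con = 0`. "Without fusion" is interpreted as running on `E_g` alone:
with the fusion step removed there is a single block by definition.

## Numerical choices

- **Heat kernel**: computed by symmetric eigendecomposition
  `V·exp(−αΛ)·Vᵀ`, exact to machine precision; tests verify agreement with
  direct Taylor-series summation to ≤ 1e-8 and mass conservation to ≤ 1e-8.
- **Katz**: closed form `(I − βA)^{−1} − I` by dense solve; the truncated
  path-sum route is kept as an independent cross-check. The truncated sum
  agrees with the closed form to 1e-6 only where the geometric tail allows
  it (`(βρ)^{l_max+1}/(1−βρ) < 1e-6`), so equivalence checks draw
  `β·ρ(A) ≤ 0.2` at `l_max = 8`.
- **Ties**: K-nearest-neighbour selection and microenvironment ranking both
  break ties by the smaller index (stable sorts), making graphs and
  memberships reproducible across runs and platforms.
- **Degenerate inputs**: isolated nodes get self-loop degree 1 in `Â_n`;
  zero-variance feature columns standardize to 0 rather than NaN;
  zero-depth spots are warned about and left as zero vectors; `β ≥ 1/ρ(A)`
  is shrunk with a warning instead of diverging.
- **Losses**: binary cross-entropies are evaluated in softplus/logit form,
  never through `log(sigmoid(·))`; at a zero discriminator both contrastive
  terms equal `log 2` exactly, which the tests assert to 1e-9. Analytic
  gradients (hand-derived backpropagation) are verified against central
  finite differences.
- **Reconstruction loss scale**: the per-spot *mean* is the default (keeps
  `α_rec = 1` meaningful across slide sizes); the plain sum is available
  via `reduction = "sum"`.
- **Determinism**: one integer seed drives weight initialization, per-epoch
  corruption permutations, clustering restarts and the generator; two runs
  with the same config are bit-identical.

## The synthetic generator

`synthetic_spec()` / `generate_synthetic()` emulate an annotated slide: a
regular grid of spots, domains as contiguous bands (cortical-layer-like;
`layout = "mosaic"` gives Voronoi patches for tumour-like mosaics),
negative-binomial counts (`size = 1/dispersion`) with lognormal per-spot
depth, domain-specific marker genes whose mean is multiplied by
`exp(marker_log_fc)`, and a histology raster tinting each spot's pixel
block with a domain base colour plus Gaussian noise. Defaults — 10×30
grid, 3 domains, 300 genes, 30 markers/domain, log-FC 1.5, dispersion 0.3,
depth 5000 — are chosen to resemble a small annotated Visium crop with
clearly separated layers.

`marker_log_fc` is the *single* domain effect-size knob: the image tint
contrast scales linearly with it, reaching the full palette at the
reference value 1.5 and vanishing at 0. A null slide (`marker_log_fc = 0`)
therefore carries no domain signal in any modality, and weaker expression
contrasts come with proportionally weaker morphology, which keeps
"difficulty" a one-dimensional notion. Marker boosts are deliberately not
renormalized to constant expected depth, so the ratio of raw-count means
across domains estimates `exp(marker_log_fc)` directly.

What the generator does *not* emulate: cell-type mixtures within spots,
platform artefacts (lateral diffusion, bead swapping), stain variation,
irregular tissue boundaries, or realistic histology texture. Passing the
recovery tests therefore demonstrates that the machinery is wired
correctly and can exploit coherent multimodal domain signal — not that the
method attains any particular accuracy on real tissue.

## Problem sizes used in tests

Module tests run on graphs of 5–50 nodes where brute-force oracles
(exhaustive KNN enumeration, Taylor-series matrix exponentials, direct
path sums, finite differences) are exact and fast. End-to-end recovery
runs use the generator defaults (300 spots, 300 genes, ~360 fused
dimensions, 500 epochs), small enough to train in about a minute per fit
on one CPU while leaving the model architecture at its defaults.

## Known limitations

- Training is full-batch and dense: memory grows as `O(N²)` through the
  kernel/adjacency matrices and compute as `O(N²·hidden)`; slides beyond
  ~10⁴ spots need mini-batching or sparse/Krylov kernels, which v1 does not
  implement.
- The pretrained-CNN image backbone is an interface (`backbone` accepts any
  function); the built-in descriptor is colour/intensity statistics and
  will not capture texture the way a deep network does.
- Embeddings are transductive — there is no `predict(newdata)`.
- The microenvironment cutoff is a fixed size `n_sub`, not a signal
  threshold; very heterogeneous spot densities may warrant an adaptive
  cutoff.
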