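---
title: "Graph-embedding ensembles for lncRNA–miRNA interaction prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-embedding ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long non-coding RNAs (lncRNAs, >200 nt) act as decoys and sponges for
miRNAs (20–25 nt); knowing which pairs interact (LMIs) illuminates both
molecules' functions. Wet-lab confirmation is slow, so the practical task is
ranking the unlabeled cells of a lncRNA × miRNA matrix so that true
interactions concentrate at the top. `emblink` treats this as transductive
link prediction on a heterogeneous network built purely from sequences and
known interactions — deliberately avoiding expression profiles and target
genes, which are unavailable for many entities.

# The model

## Heterogeneous network

Given `r` lncRNAs and `t` miRNAs with binary interaction matrix `A`
(`r x t`), each entity kind gets a sequence-similarity graph:

1. **5-spectrum features.** Counts of all overlapping 5-mers over
   {A, C, G, U} (`4^5 = 1024` dimensions). DNA input is normalized to the
   RNA alphabet at read time; a single internal alphabet serves both kinds.
2. **Linear-neighborhood similarity (LNS).** Spectra are L2-normalized —
   removing the gross length disparity between lncRNAs and miRNAs — and each
   entity's vector is reconstructed from its `kappa` (default 10) nearest
   neighbors by weights solving
   `min ||x_i - sum_j w_ij x_j||^2 + lambda ||w||^2` subject to `w >= 0`,
   `sum w = 1`. The weights are found exactly by a Lawson–Hanson-style
   active-set iteration on the KKT system (the problems are tiny and
   strictly convex for `lambda > 0`; default `lambda = 1e-6` is purely a
   numerical stabilizer). Rows of the resulting similarity matrix are
   probability vectors; entities with identical spectra fall back to uniform
   weights rather than erroring.
3. **Top-k sparsification.** Per row the 10 largest similarities are kept
   (ties broken toward the lower index, making results order-stable) and the
   graph is symmetrized by elementwise maximum. Whether the original
   construction symmetrized is not documented anywhere we could find; we
   chose max-symmetrization so that one undirected network feeds all five
   embedding algorithms, and expose `symmetrize = FALSE` so the alternative
   remains testable.

The heterogeneous network is the block matrix
`H = [[W_l, A], [A', W_m]]`, with similarity weights and unit interaction
weights side by side, unrescaled. Node order is always lncRNAs first.

## Five embeddings

All methods produce an `(r+t) x theta` matrix (default `theta = 120`) in
the node order of `H`:

* **Laplacian eigenmaps** — generalized eigenvectors of `(D - H) v = lambda D v`
  for the smallest nonzero eigenvalues, computed via the symmetric-normalized
  Laplacian; columns are D-orthonormal and exclude the constant vector.
* **GraRep** — truncated SVD (`U sqrt(Sigma)`) of the positive log
  transition statistics `max(log(P^s_ij / colsum_j) + log n, 0)` for steps
  `s = 1..k` (default `k = 1`), blocks concatenated.
* **HOPE** — rank-`theta/2` SVD of the Katz proximity
  `(I - bH)^{-1} bH`, source and target factors concatenated. The paper-side
  choice of proximity is not fixed; Katz is HOPE's canonical one. The decay
  must satisfy `b < 1/rho(H)`; the default `b = 0.5/rho(H)` sits safely
  inside the convergence region.
* **DeepWalk** — skip-gram with negative sampling trained on truncated
  random walks (walk length 80, 30 walks per node, window 30 by default;
  5 negatives, 5 corpus passes). Walks use degree-normalized transition
  probabilities of the weighted `H`. The walk generator and the SGNS loop
  are compiled (Rcpp) with a self-contained RNG, so corpora and embeddings
  are bit-reproducible given the seed.
* **Graph autoencoder** — two-layer GCN encoder (identity features, hidden
  width 512, symmetric-normalized adjacency with self-loops) with an
  inner-product decoder; variational by default. The reconstruction loss is
  the class-weighted binary cross-entropy over the full node grid with the
  standard positive upweighting — we train against the full grid rather than
  re-sampling one negative per positive each epoch because at these problem
  sizes the full-grid loss is cheap, deterministic given the seed, and is
  the reference semantics of the original autoencoder formulation. Trained
  full-batch with Adam (rate 0.01, 200 epochs).

Spectral sign/rotation ambiguity is accepted; every test that touches
LE/GraRep/HOPE output asserts Gram matrices or similarities, never raw signs.

## Two ensemble heads

A pair is represented by concatenating its two node embeddings (width
`2 theta`).

**Prediction integration** (`fit_stacked_ensemble()`): one probability
random forest per embedding method, combined by an L2-regularized logistic
regression over the five base scores. The mapping is fit on *out-of-fold*
base scores from an inner split of the training fold; fitting it on
in-sample scores would systematically overweight the most overfit base
predictor. The original description specifies the logistic mapping but not
how its training scores are produced; the out-of-fold protocol is our
resolution and the base predictors are refit on the full training fold for
test-time scoring.

**Feature integration** (`fit_attention_ensemble()`): a deep attention
network merges a chosen subset of embedding views (default GraRep + LE)
with one trainable scalar weight per view and entity kind, softmax-
parameterized so weights are positive and sum to one; the merged pair
feature `[L_i; M_j]` passes through fully connected ReLU layers (default
{240, 120}; the alternate {120, 60} preset is available via
`dann_hidden`) to a sigmoid output trained with mean binary cross-entropy
over the training grid — interacting pairs positive, all other pairs
negative, no subsampling. Plain full-batch gradient descent updates every
parameter including the attention logits. A random forest (default 2000
trees) on the merged pair features produces the final scores. Setting
`attention = FALSE` freezes the merge at the unweighted sum of views — the
no-attention ablation — and is exactly the `K`-uniform special case rather
than a separate code path.

When the desired pair-feature width differs from `2 theta`, a per-view
linear projection (trained jointly with the network) maps each view to half
the pair width; with 120-dimensional embeddings and a 160-dimensional pair
feature this means a projection to 80 dimensions. A trained projection is
the minimal construction satisfying both stated dimensions; truncation or
re-learning smaller embeddings would discard information or change the
embedding objective.

## Evaluation

Cross-validation is over the full `r x t` pair grid (default 5 folds,
stratified so fold sizes and per-fold positive counts each differ by at most
one; the full protocol supports 20 repeats). **For every fold, the fold's
positive edges are removed from the interaction block before the network is
embedded** — embeddings trained on test edges would leak labels, and any
faithful evaluation requires this even though the point is easy to miss.
The similarity graphs depend only on sequences, so they are computed once.

Metrics: AUPR by the step-wise average-precision convention (trapezoidal
interpolation is optimistically biased at ~2% prevalence), AUC by the
tie-corrected rank statistic, and F1/ACC/REC/SPEC/PRE at a fixed threshold
(default 0.5; the original threshold is unstated, so these are reported but
never asserted against external values). Top-K precision/recall tables and
a network-sparsity experiment (removal ratios 0.1–0.4, deleted links
becoming unlabeled) complete the harness.

# The synthetic benchmark

`simulate_lmi_data()` plants co-interacting blocks: each block has an
i.i.d. uniform ancestor sequence per entity kind; members are substitution-
mutated copies (no indels, keeping the k-mer algebra simple and the signal
strength a single dial); links are Bernoulli — within-block probability 0.5,
cross-block 0.02 by default (sized so ~2 in 10 pairs of the grid interact
within blocks, echoing the sparsity regime of curated LMI collections at
reduced scale with 60 lncRNAs × 30 miRNAs in 3 blocks).

What it emulates: sequence similarity informative for shared partners,
bipartite sparsity, and the transductive setting. What it does not:
real phylogenetic relatedness structure, binding-site (seed-match)
mechanics, expression covariates, database ascertainment bias. Passing the
planted-recovery tests therefore shows the pipeline can extract a
similarity-plus-topology signal, not that it reaches any particular
performance on curated data.

One property of the generator is worth stating precisely: given the blocks,
links are independent Bernoulli draws, so no scorer can rank a held-out
within-block non-link below a held-out within-block link except by chance.
The best achievable held-out AUC equals that of the true block-indicator
scorer. With the default geometry (one third of pairs within blocks,
`p_within = 0.5`, `p_cross = 0.02`) this ceiling is about 0.86 — an
intrinsic identifiability limit of the benchmark, not a property of any
model. Results on the fixture should be read against that ceiling.

# Problem sizes and numerical choices in the shipped experiments

The package's own tests and the acceptance script run at fixture scale
through `lmi_params_demo()`:

* embedding dimension 12 — the same ~13% of the node count as the
  full-scale default (120 of 917);
* DeepWalk: walk length 40, 10 walks per node, window 5, 3 passes;
* autoencoder hidden width 64, 200 epochs;
* attention network hidden {48, 24}, trained 2000 epochs at rate 0.1 —
  at 1440 training pairs the stated full-scale schedule (rate 0.01,
  200 epochs) leaves the loss far from its plateau and the attention logits
  essentially at initialization, so the demo preset trains to convergence;
  this is a numerical choice, selected from the loss trace;
* forests of 300 trees with a 3-fold inner split for the stacking scores.

Degenerate inputs: zero-degree nodes are rejected before any transition
matrix or Laplacian pencil is formed; isolated nodes in the walk generator
produce self-repeating walks; identical spectra yield uniform LNS weights;
a diverging autoencoder or attention network aborts with the last finite
loss; `log(0)` cells of the GraRep statistics are clipped to zero along
with the rest of the negative log mass.

# Known limitations

* Attention weights are per-view scalars shared across entities — the merge
  has no per-entity adaptivity, by design.
* The evaluation is transductive: nodes unseen at training time cannot be
  scored (no inductive embedding).
* At heavy class imbalance the fixed 0.5 threshold makes the binary metrics
  blunt instruments; rank metrics (AUPR/AUC) are the primary outputs.
* The ceiling analysis above means fixture AUCs saturate near 0.86; only
  relative comparisons between methods are meaningful near saturation.

# Reproducing a full-scale analysis

The curated inputs used at full scale are the lncRNASNP interaction
collection with NONCODE lncRNA and miRBase miRNA sequences (3784
interactions between 642 lncRNAs and 275 miRNAs after dedup and sequence
matching in the original compilation; current releases will differ).
Download the FASTA and interaction files from those resources, write a YAML
config pointing at them (see `read_pipeline_config()`), keep the default
`lmi_params()` (the full-scale settings), and run

```sh
Rscript inst/cli/emblink evaluate --config config.yaml
```

with `repeats: 20` for the 20×5-fold protocol. On data of that composition,
AUPR in the 0.65–0.70 range for the ensemble heads is the documented
ballpark; it is not asserted by any test here because the external
databases drift between releases.
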