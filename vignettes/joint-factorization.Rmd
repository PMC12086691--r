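---
title: "Joint factorization of spatial expression and histology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint factorization of spatial expression and histology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the decisions
behind the implementation, and what its tests do and do not establish. It
states no empirical result that the test suite does not itself compute.

# The model

`spotfuse` factorizes two non-negative matrices over the same spots — a
spot×gene expression matrix $Y_{rna} \in \mathbb{R}_+^{m \times n}$ and a
spot×feature image matrix $Y_{img} \in \mathbb{R}_+^{m \times f}$ — into a
shared score matrix and two loading matrices:

$$\min_{W, H_{rna}, H_{img} \ge 0}\;
  \alpha\,\lVert Y_{rna} - W H_{rna}\rVert_F^2
  + (2-\alpha)\,\lVert Y_{img} - W H_{img}\rVert_F^2 .$$

The shared $W$ is the point of the model: a spot's factor scores must
reconcile both its transcriptome and its local morphology. The modality
weight $\alpha \in [0,2]$ defaults to 1.0 — equal weighting. Without a
ground truth we recommend sweeping a few values near 1.0 (e.g. 0.8, 1.0,
1.2); with annotations, the `evaluate` CLI subcommand scores an
$\alpha$-grid by ARI/AMI/Fowlkes–Mallows.

**Assumptions.** Both inputs are non-negative and spot-aligned;
factorization is parts-based (additive, no cancellation); spots are
exchangeable — the model has no explicit spatial term. Spatial coherence
in the factors arises only from spatial coherence in the data.

## Modality rescaling (an open design point, decided)

Nothing pins down the relative numeric scale of counts and pixel-histogram
features, and with raw units $\alpha = 1$ would *not* weight the
modalities equally. Decision: by default each matrix is divided by its own
Frobenius norm before fitting (`modality_rescale = TRUE`); the two
divisors are stored on the model and folded back into the returned
loadings, so `W %*% H_rna` lives on the input scale while the objective
trace is reported in the solver's rescaled space. Turn the flag off to
reproduce raw-unit behaviour.

Similarly, whether counts should be normalized or log-transformed before
factorization is left to the user: the solver takes the matrix as given,
and the CLI exposes `--normalize` (per-spot total-count scaling) and
`--log1p` as explicit flags, both off by default.

# The solver

Each outer iteration solves three convex subproblems in turn — $W$ with
both loadings fixed, then each loading with the rest fixed — by
hierarchical alternating least squares: cyclic closed-form updates of one
column of $W$ (or row of $H$) followed by projection onto the
non-negative orthant. The $W$-step operates on the weighted concatenation
$[\sqrt{\alpha}\,Y_{rna}\,|\,\sqrt{2-\alpha}\,Y_{img}]$, whose Gram
matrices are accumulated per block; the two $H$-steps are independent
given $W$.

**Acceleration.** After the (expensive) Gram precomputation, cyclic
sweeps are cheap, so each block update repeats them while the per-sweep
objective decrease exceeds a fraction `accel_delta` (default 0.01) of the
first sweep's decrease, capped at $1 + \lfloor \rho \cdot
(\text{precompute cost} / \text{sweep cost}) \rfloor$ sweeps with
`accel_rho` = 0.5. The per-sweep objective is evaluated through the
cached Gram matrices, so monitoring costs $O(k^2 \max(m,n))$, not a full
residual.

**Stopping.** Relative decrease of the exact joint objective below
`rel_tol` (default 1e-6), or `max_outer_iter` (default 200). Both are
scale-invariant, which the $\alpha = 2$ equivalence test relies on.

**Zero-column rescue.** HALS can drive a factor column of $W$ to zero.
If a column norm falls below 1e-12 the column is re-seeded from a
half-normal draw scaled to the mean surviving column norm, with a
warning, keeping the rank at the requested $k$. The matching rows of
*both* loading blocks are zeroed at the same moment: a re-seeded column
against stale non-zero loadings could increase the objective, and the
monotone objective trace is a package invariant (asserted for every fit
in the suite, tolerance $10^{-9}$ relative).

**Degenerate weights.** $\alpha = 2$ (expression-only) and $\alpha = 0$
(image-only) take exactly the unimodal code path: the zero-weight block is
excluded from every update and from the objective, and its loadings are
fit post hoc by one non-negative least-squares pass against the final
$W$, flagged in `model$unweighted_blocks`. The suite asserts per-iteration
equality ($\le 10^{-10}$) between the $\alpha = 2$ joint fit and the fit
on expression alone.

**Scale convention.** The factorization is invariant to
$W \to W D^{-1}$, $H \to D H$ for positive diagonal $D$. After
convergence, columns of $W$ are normalized to unit Euclidean norm and the
same diagonal is pushed into both loading blocks, so $W$ is comparable
across runs and directly usable as clustering input.

# Initialization

* `random_halfnormal` (default): entries $|z| \cdot s \cdot c$ with $z$
  standard normal. The magnitude $c = \sqrt{\overline{Y}_{joint} / k}$
  makes the initial product match the data's mean magnitude — no scale is
  prescribed for this anywhere, and an ill-scaled start wastes early
  iterations. A seed is required; the draw is a pure function of
  (shape, seed, scale).
* `nndsvd`: the deterministic double-SVD construction from the $k$
  leading singular triplets, keeping for each triplet the dominant of the
  positive/negative part pairs, zeros left as zeros (the plain variant —
  no mean or random filling; HALS tolerates exact zeros). For the joint
  problem NNDSVD runs on the weighted concatenation — exactly the
  equivalent unimodal problem — and the loading block is split and
  un-weighted afterwards. Whether the two blocks should instead get
  per-modality SVDs is genuinely open; the concatenation choice preserves
  the objective equivalence used by the oracle tests, which is why it was
  taken.

Random initialization remains the default (deterministic NNDSVD can bias
the solution toward SVD-like structure), but NNDSVD is used inside
bi-cross-validation for fold determinism, and for the exact-recovery
tests where its fast error decay matters.

# Rank selection by bi-cross-validation

The expression matrix is randomly permuted and tiled into
$\begin{pmatrix} A & B \\ C & D \end{pmatrix}$; $D$ is factorized at rank
$k$ and the held-out block is predicted by the Owen–Perry estimator
$\hat A = B H_D^+ W_D^+ C$ with least-squares pseudo-inverses, robust to
rank deficiency. The reported error is per-held-out-cell MSE, so folds
and partition shapes are comparable. The prediction is invariant to the
diagonal scale ambiguity of $(W_D, H_D)$ — asserted to $10^{-10}$ in the
suite. The method itself states the block scheme but not the prediction
algebra; the Owen–Perry form is the standard estimator consistent with
"predict A from D via B and C", and that choice is recorded here.

Defaults (not prescribed anywhere, chosen once): `row_frac = col_frac =
0.5`, `folds = 5`, NNDSVD refits inside folds. Partitions are shared
across the $k$-grid within a fold so the error curve is not confounded by
partition noise. `k_selected` is the grid argmin of the mean error, ties
broken toward the smaller rank (which.min's first-minimum rule). BCV runs
on the expression matrix only, matching the stated method; to select on
both modalities, pass the weighted concatenation explicitly.

# Image features

For each spot, square patches centred at its full-resolution pixel
coordinate are cut at several scales (multiples of the spot diameter),
and each patch is summarized by per-channel intensity histograms:
`n_bins` equal-width bins over [0, 255], last bin right-closed,
concatenated channel-major. Features are pixel *counts* — integers,
non-negative by construction, and conserved: per channel they sum to the
patch's actual pixel count.

Decisions, all configurable and logged into run metadata:

* **Scales** default to {0.5, 1, 2}× the spot diameter — sub-spot,
  at-spot and context scales inside the supported (0, 3] range. The
  context scale deliberately reaches into the inter-spot gap, where
  morphology carries information expression cannot.
* **Bins** default to 10 per channel (the conventional histogram-feature
  setting), so the default feature count is 3·3·10 = 90.
* **Borders**: patches are clipped to the image, never padded;
  conservation is then against the clipped count. Padding would
  manufacture pixel mass that was never observed.
* **Coordinates** are 0-based (row, col) full-resolution pixels; when a
  scale-factor descriptor accompanies a down-sampled image, coordinates
  and spot diameter are multiplied through before patching. The spot
  diameter comes from the descriptor when present, else an explicit flag
  (legacy ST arrays ship no descriptor).
* **Formats**: PNG via the `png` package plus plain-text PPM. No TIFF
  reader exists in the supported dependency set, so TIFF input is
  rejected with a conversion hint rather than half-supported.

User-supplied features (e.g. CNN embeddings) bypass extraction through
`load_user_features()`, which validates non-negativity and re-orders rows
to the expression barcodes.

# Postprocessing conventions

* Graph clustering is "community detection on a kNN graph of W rows with
  a resolution parameter" — implemented with igraph's Leiden on the
  modularity objective. The exact refinement algorithm is not part of the
  contract.
* ARI, AMI (permutation-model expected MI, arithmetic-mean
  normalization) and Fowlkes–Mallows are implemented from the
  contingency table and verified against brute-force pair-counting and
  exhaustive-permutation oracles. Conventions for degenerate partitions:
  identical trivial partitions (both one cluster, or both all singletons)
  score 1; a vanishing AMI denominator yields 0 unless MI exceeds its
  expectation.
* Spots lacking a reference annotation are dropped from metrics and
  counted in the result's attributes — sparse annotations are the norm,
  and silently scoring unannotated spots as errors would be wrong.
* Correlation of a constant factor (or target) is defined as 0 with a
  warning, not NaN: factors can legitimately die and pipelines must not
  crash.
* Signature scores are mean set expression minus the mean of an
  expression-matched control set (genes binned by average expression,
  controls sampled per set gene under a seed).

# The synthetic generator: a stated world

`simulate_joint_data()` plants $k$ contiguous rectangular regions on a
near-square spot grid. $W_{true}$ is half-normal with a dominant column
for the spot's own region; loadings are i.i.d. half-normal; data are
signal plus Gaussian noise scaled to a requested SNR (variance ratio) and
clipped at zero. Defaults — m = 150, n = 200, f = 90 (matching the
default feature extractor), k = 4, SNR 5 per modality — were chosen once
as a realistic mid-noise regime for normalized spot data and are not
tuned against test outcomes. A Poisson option exists for count realism;
the acceptance suite uses Gaussian noise because its SNR is analytic.
`simulate_tissue_image()` paints each region a distinct hue with
per-pixel jitter so patches separate by their histograms.

What the generator does **not** emulate: histology texture (nuclei,
glands — regions are flat colour plus noise), spatial autocorrelation
within regions, count overdispersion beyond Poisson, platform artefacts
(spot dropout, diffusion), or irregular region geometry (a Voronoi option
would add realism but the rectangular default is trivially verifiable).
A green end-to-end test therefore establishes that the pipeline recovers
planted block structure under controlled noise — not performance on real
tissue.

# Numerical choices and degenerate inputs

* Objective values are computed through Gram identities
  ($\lVert Y\rVert^2 - 2\langle P, H\rangle + \langle Q, HH^T\rangle$)
  and clamped at zero against rounding.
* Columns with vanishing Gram diagonal are skipped in sweeps (the rescue
  handles truly dead factors).
* All-zero input matrices are rejected; negative entries are rejected at
  container construction with the offending location named.
* `k > min(m, n)` warns (over-parameterized) but proceeds.
* Every random stage — initialization, rescue, BCV partitions, k-means,
  Leiden, control-gene sampling — runs under a locally scoped seed, so
  library calls never perturb the caller's RNG stream and identical seeds
  give identical results (the CLI writes byte-identical outputs on
  rerun).

# Known limitations

Two modalities only (more would require generalizing the weighted
concatenation); the solver densifies sparse input; no explicit spatial
model; no GPU path; TIFF unsupported; BCV considers the expression matrix
only by default. Enrichment analysis, external reference integration and
competitor benchmarking are out of scope for this package.
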