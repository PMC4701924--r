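---
title: "Voxelwise connectivity graphs with bounded memory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise connectivity graphs with bounded memory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelgraph)
```

## The problem

In resting-state fMRI, functional connectivity between two voxels is
usually measured as the Pearson correlation of their BOLD time series.
Treating every in-brain voxel as a graph vertex and every supra-threshold
correlation as an edge yields a voxelwise brain graph whose per-vertex
metrics — degree, clustering coefficient, PageRank, component membership —
map back onto the brain as interpretable images. The obstacle is scale: a
modern whole-brain mask at 2 mm resolution holds roughly 228,000 voxels,
so the dense correlation matrix occupies

$$ V^2 \cdot 8 \;\text{bytes} \approx 388\ \text{GiB} $$

in double precision (`memory_footprint(228200, 8)`), far beyond commodity
RAM. voxelgraph never materializes that matrix. It computes the matrix in
contiguous row-block *tiles* under an explicit byte budget, immediately
reduces each tile to its threshold-surviving entries, and discards it.
Only the sparse edge list and the per-voxel metric vectors persist.

## Pipeline model

For one subject the pipeline is

1. **Masked ingestion.** The 4D NIfTI image is read in chunks of
   `chunk_volumes` volumes; each chunk contributes its in-mask voxels to a
   T×V matrix (time in rows, voxels in columns — every downstream step
   assumes this orientation). Intensities are promoted to 64-bit doubles;
   NIfTI `scl_slope`/`scl_inter` scaling is applied by the reader. The
   result is exactly invariant to the chunk size; chunking only bounds the
   read buffer.
2. **Standardization.** Each column is centered and scaled to unit sample
   standard deviation (denominator T−1). The Pearson correlation between
   voxels i and j is then the dot product of their columns divided by T−1,
   which is what makes tiled evaluation a sequence of dense products.
3. **Tiling.** `plan_tiles(V, 8, budget)` partitions the V×V matrix into
   row blocks of height `floor(budget / (8V))`; the block count is
   `ceil(V / height)`. At V = 228,200 and a 4.2 GiB budget this yields
   93 tiles of height 2,470.
4. **Threshold streaming.** Each tile is evaluated, pairs i < j with
   |r| ≥ threshold are appended to the edge list with their signed r, and
   the tile is freed. The comparison is closed (≥) on the absolute value.
5. **Graph metrics.** The unweighted graph over all V vertices (vertex id
   = 0-based x-fastest linear index of the mask grid) gets per-vertex
   degree d, triangle count tc, local clustering coefficient
   tc/(d(d−1)/2), PageRank, and connected-component labels, all writable
   as NIfTI maps in the mask geometry.

Group analysis stacks subjects' tables over a shared mask (rows
concatenated in input order) and decomposes the stack with a truncated
SVD; right singular vectors are voxel maps.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | — | absolute-correlation cutoff in (0,1); 0.6 is a common choice for voxelwise graphs |
| `target_S` | — | alternative to a fixed threshold: pick the largest grid threshold whose edge-density statistic S = log E / log K (K = 2E/N average degree) meets the target; S is log-base invariant and comparable across heterogeneous datasets |
| `tile_budget_bytes` | 512 MiB | maximum bytes per dense tile; trades peak memory against the number of passes |
| `chunk_volumes` | 32 | volumes per read; bounds ingestion memory only |
| `damping` | 0.85 | PageRank damping; with `tol = 1e-8` (L1) and `max_iter = 200` |
| `k`, `center` | — | truncated-SVD rank; `center` subtracts column means first, turning the decomposition into a PCA |

## What the synthetic generator emulates

`generate_bold()` realizes a latent-factor model: voxel v in community c
follows $a\,L_c(t) + \sigma\,\varepsilon_{vt}$ with independent
standard-normal community signals $L_c$ and voxel noise. Expected
correlations have closed form — $\rho_\text{within} = a^2/(a^2+\sigma^2)$
within a community, 0 between — so every pipeline stage can be checked
against ground truth. Generation is O(V·T); no V×V covariance is ever
factorized. Communities are contiguous blocks in linear-index order by
default, so metric maps are visually checkable.

The generator's default conditions are the validation conditions used
throughout the test suite: a 10×5×5 grid fully covered by 5 communities of
50 voxels, T = 400 volumes, amplitude 3, noise 1 (ρ_within = 0.9). At
these settings a 0.6 threshold recovers the 5 communities as exactly 5
non-singleton connected components of 50 vertices with within-community
clustering ≈ 1, across seeds: the within-community sample correlation at
T = 400 has standard error ≈ (1−ρ²)/√T ≈ 0.01, far from the cutoff, while
between-community correlations (se ≈ 0.05) essentially never reach 0.6.

What the generator does **not** emulate: hemodynamic response shapes,
temporal autocorrelation, motion and physiological artifacts, spatial
smoothness of real BOLD noise, or scanner drift. Passing the recovery
tests therefore demonstrates the pipeline's correctness as a computation,
not robustness of any neuroscientific inference on real data.

## Numerical choices

- **Bit-exact tile-plan invariance.** Each tile row is computed as one
  matrix-vector product against the full standardized table rather than
  as part of a blocked matrix-matrix product. Blocked BLAS kernels change
  summation order with the tile height, which would make streamed edge
  lists differ in the last ulp between plans; the per-row product makes
  row i's result a function of i alone, so any two valid plans produce
  identical bytes. Correlations are clipped to [−1, 1] after the product.
- **Zero-variance voxels.** Constant time series (common at mask edges)
  standardize to all-zero columns: their correlation with everything is
  exactly 0, never NaN, and their positions are reported.
- **Degree < 2 clustering.** The coefficient divides by d(d−1)/2, which
  is 0 for isolated and leaf vertices; their coefficient is defined as 0.
- **Component labels** are the minimum vertex id of each component
  (union-find, merging larger roots under smaller), so labels are stable
  and idempotent under recomputation.
- **PageRank** treats each undirected edge as two directed edges, gives
  dangling (isolated) vertices uniform redistribution, and normalizes the
  result to sum 1 (the probability convention; some graph engines return
  scores summing to N). Non-convergence raises an error with the last
  residual rather than returning a silent partial answer.
- **Threshold selection** exploits monotonicity: edge count is
  non-increasing in the threshold, so a single tile pass bins |r| against
  the whole descending grid and every grid point's E (hence S) comes from
  one sweep. Ties break toward the larger threshold.
- **Truncated SVD** is randomized subspace iteration: a Gaussian sketch
  (seeded, k + max(10, k) columns) refined by alternating products with
  the matrix and its transpose, QR re-orthonormalized each round,
  stopping when the top-k Ritz values are stable to 1e−12 relative. Only
  matrix-vector work against the data is needed, keeping the method
  usable when V rules out a dense decomposition. The small projected
  problem is solved densely; signs are fixed so each right vector's
  largest-magnitude loading is positive.
- **Mask binarization** is `value > 0`; qform is preferred over sform
  when both are present.

## Design decisions on genuinely open points

- The tile-count arithmetic for a whole-brain matrix depends on how input
  buffers are accounted against the device budget, which has no single
  right answer; `plan_tiles` therefore takes the budget explicitly and
  documents its accounting (output tile only). At a 4.2 GiB budget the
  whole-brain matrix splits into 93 tiles.
- Whether intensity scaling is applied on read is left implicit in some
  toolchains; voxelgraph applies it, since unscaled integers are storage
  artifacts, and correlations are scale-invariant per voxel anyway.
- Thresholding uses |r| (negative correlations count); the edge stores
  the signed r so a sign-sensitive analysis can filter afterwards, but
  all graph metrics here use the unweighted graph.
- The CLI stores intermediate tables as plain TSV with JSON header lines:
  open, diffable, and exactly round-tripping doubles at 17 significant
  digits.

## Validation problem sizes

The test suite validates at sizes where independent oracles are cheap and
exact: tiled correlation against per-pair Pearson on tables up to 200
voxels × 100 time points over 20 seeds and 3 tile plans each (agreement to
1e−12, plan invariance bit-exact); graph metrics against BFS, dense
triple-product and dense power-iteration oracles (plus igraph
cross-checks) on 50 random graphs up to 500 vertices; planted-community
recovery on the default generator conditions across 20 seeds; and the
truncated SVD against a dense decomposition of 200×500 matrices at 1e−8.
These sizes exercise every code path — multiple tiles, empty graphs,
isolated vertices, zero-variance voxels — while keeping the whole suite
in the tens of seconds.

## Known limitations

- The tile loop is serial; the tiling contract is designed so a
  multi-process or GPU backend could replace it, but none ships here.
- No Fisher z-transformation, partial correlation, or regularized
  covariance estimation — the connectivity measure is plain Pearson (or
  cosine) only.
- Graph metrics are unweighted; weighted clustering or centrality
  variants are out of scope.
- NIfTI-1 single-file images only (no NIfTI-2, CIFTI, DICOM), and no
  preprocessing: the input is assumed motion-corrected and registered.
- Union-find and the edge-list loader hold the edge set in memory; graphs
  beyond a few hundred million edges need a different representation.
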