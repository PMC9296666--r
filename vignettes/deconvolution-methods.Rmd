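---
title: "Methods: cell-type deconvolution against a single-cell reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type deconvolution against a single-cell reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decomap)
```

## The model

`decomap` treats a tumour cluster's pseudobulk expression profile
$m \in \mathbb{R}^G_{\ge 0}$ as an approximate non-negative combination
of reference cell-type profiles,

$$ m \;\approx\; S\,w, \qquad w \ge 0, $$

where $S$ is a genes × cell-types *signature matrix* of average
normalized expression and the reported *relative fractions* are
$w / \sum_j w_j$. Two assumptions are load-bearing:

* **Linearity on the signature scale.** Both $S$ and $m$ are average
  log1p-normalized expression (counts per 10k, `log1p`). Averaging log
  values and then mixing is not the same as mixing raw transcript
  pools; what the model really asserts is that on whatever common scale
  the signature and the mixtures are expressed, the mixture is a convex
  combination. Using the same normalization pipeline for the reference
  and the tumour side is therefore essential, and the package's
  simulators generate mixtures on exactly this scale.
* **Completeness of the reference.** A regression onto $S$ can only
  distribute mass over the columns it is given. The atlas must contain
  every lineage the tumour may resemble — the reason the emulated
  reference spans embryonic through adult timepoints.

## Pipeline stages and their parameters

### Cell QC (`qc_filter_cells`)

| rule | default | semantics |
|---|---|---|
| min detected genes | 1000 | strict `<` removes the cell |
| mitochondrial fraction | 0.10 per sample | strict `>` removes; threshold settable per sample (typical practice is 5–15%) |
| high-count doublets | median + 4·SD | per-sample, computed on cells surviving the first two rules; 4–5 SD is the conventional band, 4 is the default |

The doublet rule is applied exactly once rather than iterated to a
fixed point: iteration would re-shrink the SD after each removal and
make the removal set depend on convergence details; a single pass is
deterministic and reproducible. The mitochondrial fraction is computed
on raw counts (counts of `mt-`-prefixed genes over total counts) — the
standard choice; nothing downstream depends on the alternative. The
six sex-linked genes (Xist, Tsix, Eif2s3y, Ddx3y, Uty, Kdm5d) are
removed after cell QC and before normalization, so sex effects cannot
enter library-size factors of the normalized data; their removal does
not change detected-gene counts used by QC.

### Normalization (`normalize_log1p`)

`log1p(count / total * scale_factor)` with `scale_factor = 1e4`, the
conventional value for global-scaling normalization. The transform
preserves the zero pattern and `colSums(expm1(X))` equals the scale
factor for every cell — both are tested invariants.

### Cell-cycle gate (`gate_g0_g1`)

Upstream G1/S/G2M calls are inputs (the phase classifier itself is out
of scope). Cells called G1 are kept as G1 only if Top2a or Mki67
exceeds 1 on the log1p scale (strict `>`, so a value of exactly 1 is
quiescent G0). Gene matching is case-insensitive so mouse and human
symbol conventions both work.

### Marker detection (`wilcoxon_de`)

One-vs-rest two-sided Wilcoxon rank-sum tests per cluster. Because the
one-vs-rest design pools all cells in every contrast, per-gene ranks
are computed once and reused across clusters, which makes the test
vectorizable. Two p-value routes exist:

* **exact** — the permutation distribution of the rank sum enumerated
  by dynamic programming over doubled midranks (ties handled exactly);
  used automatically when the pooled size is ≤ 30;
* **normal** — tie-corrected normal approximation with continuity
  correction, used for realistic cluster sizes.

The exact route is validated against an independent brute-force
subset-enumeration oracle; the normal route against the exact one.
Retention requires `pct_in ≥ 0.5` (fraction of cluster cells expressing
the gene), `avg_lfc ≥ 0.5`, and BH-adjusted p < 0.05. Choices worth
stating:

* The pct cutoff applies to `pct_in` only; `pct_out` is reported for
  diagnostics but not filtered on, mirroring the single-cutoff
  convention of the clustering toolkits this follows.
* `avg_lfc` is the natural log of `(mean(expm1(x)) + 1)` ratios — the
  Seurat-era convention — so the 0.5 cutoff is a natural-log cutoff.
  `rank_markers_min_pairwise_lfc`, by contrast, ranks a cluster's DE
  genes by the minimum over all *pairwise* differences of mean log
  expression (the linear-model convention), because that ranking is
  consumed as a marker ordering, not filtered by the 0.5 cutoff.
* The adjusted-p filter is applied for consistency across DE uses and
  is configurable (`padj_cutoff = 1` disables it).

### Signature assembly (`build_signature_matrix`)

Gene universe = union of retained DE genes over clusters, minus the
four excluded gene families (cell-cycle, ribosome, mitochondrial,
apoptosis — families whose expression reflects state rather than
identity), then ortholog-translated. Values are per-cluster arithmetic
means of log-normalized expression — "average normalized expression" is
taken on the log scale; the tested invariant is that every entry equals
the brute-force cluster mean to 1e-12. Clusters with fewer than 20
cells (`drop_small_clusters`, `≥` kept) are removed first: below a few
dozen cells a mean profile is dominated by sampling noise. Ortholog
translation defaults to `one_to_one_only` (sources sharing a target are
dropped); a `highest_expression` resolution is available but off by
default, since many-to-many orthology rarely carries reliable signal at
signature resolution. When the exclusion lists are given in the source
namespace and the map is injective, exclusion-then-translation equals
translation-then-exclusion (a tested property), so the order is a
convention, not a choice with consequences.

### Engines (`deconvolve`)

* **NNLS** — Lawson–Hanson non-negative least squares. Deterministic,
  exact at zero noise; serves as the oracle for the other engines.
* **ν-SVR** — linear ν-support-vector regression of the mixture on the
  signature columns (the CIBERSORT-family core), fitted at
  ν ∈ {0.25, 0.5, 0.75}; primal coefficients are clipped at zero and
  the ν with the lowest reconstruction RMSE against the standardized
  mixture wins, ties toward smaller ν for determinism. Standardization
  follows the published engine family's convention: the signature is
  z-scored *as a whole matrix* and the mixture as a vector. A single
  shared affine transform preserves the relative scale of the
  coefficients — per-column or per-gene z-scoring would distort the
  recovered proportions by each column's variance and was therefore
  rejected.
* **DWLS** — iteratively reweighted NNLS with gene weights
  `1/max((Sw)^2, damping)`, `damping = 1e-4` on the log-normalized
  scale, iterated to a 1e-8 relative sup-norm change or 100
  iterations. The damping floor keeps weights finite where the fit
  predicts zero expression.

Raw coefficients are mapped to the simplex by clipping and
sum-normalizing; an all-zero vector is returned as all zeros with a
degenerate flag rather than an error, so one empty mixture cannot abort
a batch. Fit quality (`rmse`, `pearson_r` of $Sw$ vs $m$) is reported
per mixture; a constant reconstruction yields `pearson_r = NA`.

### Match calling and reporting

The relative-abundance cutoff is 0.2 and *inclusive* (a fraction of
exactly 0.2 matches; the boundary semantics are a package convention).
Raising the cutoff can only remove matches — a tested monotonicity
contract. Overlap summaries count mixtures per exact match-set
combination (not subset sums). Hierarchical ordering of mixtures uses
Euclidean distance with average linkage by default — the defaults of
the heatmap tooling this emulates — with correlation distance and
complete/Ward linkage available; the tree is also serialized as Newick.

## What the simulators emulate — and what they do not

`simulate_atlas` draws negative-binomial counts (mean/size
parameterization, size = 2, baseline mean 0.5) with log-normal
library-size factors (sdlog 0.25), and plants disjoint marker modules:
50 markers per type whose NB mean is multiplied by 8 in that type's
cells. The default 8 types carry developmental-atlas labels (embRGP,
gliogenic, OPC, astrocyte, neuron, aNSC, qNSC, microglia) spread over
an E12→P111 timepoint axis, emulating temporally restricted precursor
states with distinguishing markers. `simulate_mixtures` forms exact
convex combinations of signature columns plus additive Gaussian noise
with per-gene SD `noise_sd × rowMean(S)`, truncated at zero — a
calibration choice (no empirical noise model is claimed), chosen so
that `noise_sd` is interpretable as a relative perturbation on the
signature scale. `simulate_fraction_truth` mixes two or three types per
mixture with symmetric Dirichlet(10) weights, i.e. a handful of types
at comparable, clearly-present proportions — matching the matching
semantics the 0.2 cutoff encodes.

Deliberately **not** simulated: doublets' transcriptional structure,
ambient RNA, batch effects, platform-specific dropout beyond what the
NB gives, and full tumour single cells (mixtures are pseudobulk).
Passing the recovery benchmarks therefore shows the pipeline is
*internally correct* — it recovers compositions generated by its own
assumed model — not that the model captures every property of real
tumour data. In particular, real mixtures violate the reference-
completeness assumption in ways no synthetic benchmark can probe.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale, chosen to exercise the
statistics without inflating runtimes: engine benchmarks at 20
reference types × 40 mixtures (markers-only signatures of 600 genes);
signature fidelity on the default 8-type atlas (200 cells/type, 2000
genes, 50 markers/type); the Wilcoxon oracle on 200 randomized
instances of up to 10-vs-10; the headline embryonic-precursor
experiment over 40 seeded replicates with a true embRGP fraction of
0.6–0.8 and qNSC absent. Noise-free NNLS recovery is asserted to 1e-6,
ν-SVR/DWLS to 0.02 absolute per fraction; signature entries to 1e-12 of
brute-force means; simplex sums to 1e-9. All generators are pure
functions of (spec, seed): identical inputs give bit-identical output,
and the RNG state of the caller is never disturbed.

## Known limitations

* Fractions are *relative* to the captured signature space; no
  absolute-abundance or purification mode is provided.
* The ν-SVR engine's batch-correction extensions (the hosted "x"
  variant of the engine family) are not reimplemented.
* The Wilcoxon normal approximation saturates at p = 1 near the center
  of the permutation distribution (continuity correction); this has no
  effect on marker retention, which operates far in the tail.
* Upstream clustering, embedding, integration and phase classification
  are out of scope: cluster labels and G1/S/G2M calls are inputs.
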