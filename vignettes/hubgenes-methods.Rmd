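---
title: "Methods: transcriptome-connectome analysis of network hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-connectome analysis of network hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations behind `hubgenes`. It is the place where
the design decisions that were genuinely open are written down.

## The analysis model

The package treats a cortical parcellation as a network of `n` regional
nodes. Per subject, functional connectivity is the Pearson correlation of
wavelet coefficients of the regional BOLD time series, pooled over a set of
wavelet scales. Binary graphs are built from the group-mean correlation
matrix at a target connection density; the maximum-correlation minimum
spanning tree is included first so the graph is connected at any density.

Community structure is estimated once, on the group graph, by consensus
over repeated randomized Louvain runs maximizing the
resolution-parameterized modularity

    Q(gamma) = (1/2m) * sum_ij [A_ij - gamma k_i k_j / (2m)] delta(c_i, c_j).

Each subject's graph is then scored against this prototypical partition:
intra- and inter-modular degree count a node's edges to its own versus
other modules; the participation coefficient is
`PC(i) = 1 - sum_m (k_i(m)/k_i)^2`; the connection distance `d(i)` is the
mean Euclidean length (mm) of the node's edges. Subject-level metrics are
averaged (mean by default; median exposed) into the `n x 3` response matrix
`C = [k_intra, k_inter, d]`. The choice of the mean is itself a decision:
with a single response matrix required downstream, the mean is the obvious
unbiased aggregate, and the median option exists for robustness checks.

Gene expression enters as a gene x region matrix, Z-scored per gene across
regions. Multi-response PLS finds gene combinations with maximal covariance
with the standardized columns of `C`. Per component the weight vector is
the dominant left singular vector of the current cross-covariance
`X'Y` — the exact fixed point of the classical NIPALS inner iteration,
computed from the 3 x 3 eigenproblem of `(X'Y)'(X'Y)` — followed by
regression deflation of both blocks. Response columns are standardized
before fitting because k_intra, k_inter (edge counts) and d (mm) carry
incommensurate units. "Variance explained" is the fraction of the total
standardized response sum of squares reproduced by each component's rank-1
reconstruction; it is non-decreasing cumulatively and reaches 100% when as
many components as observations are extracted.

Inference is nonparametric throughout:

* **Bootstrap gene ranking.** Regions are resampled with replacement, the
  model refit, and each draw's component sign-aligned to the original by
  the inner product of weight vectors. `Z = w / SE_boot(w)` ranks the
  genes. Degenerate resamples (fewer than two distinct regions, or a
  constant response column) are redrawn with a bounded retry.
* **Permutation tests.** The statistic is the cumulative percentage of
  response variance explained by the first `n_components` components. Rows
  of `C` are permuted as whole 3-vectors. The naive scheme permutes
  regions freely; the block scheme permutes spatially contiguous blocks of
  regions as units, keeping within-block order, which preserves the
  spatial autocorrelation structure under the null. The naive scheme is
  implemented as the singleton-block special case, so the two schemes
  share one code path and one seed stream. With unequal block sizes the
  region-to-row map shifts across block boundaries while within-block
  adjacency is preserved; a single block is an error. When no block labels
  are supplied, blocks are built by k-means on the region centroids with
  `round(n/10)` clusters under a fixed derived seed. P-values use the
  add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)` and can never be
  zero.
* **Enrichment.** The minimum-hypergeometric statistic minimizes the
  hypergeometric tail over all rank cutoffs (equivalently, over cutoffs
  ending at an annotated gene). The term-level p-value is exact — a
  dynamic program over the hypergeometric path lattice counting the
  probability that a random arrangement enters the rejection region — for
  lists of at most 5000 genes, and a Bonferroni bound over the attainable
  cutoffs (one per annotated gene) beyond that; exactness where tests
  operate, tractability at genome scale. Both list ends are tested by
  running the statistic on the ranking and its reversal, and BH-FDR is
  applied across all term-by-direction rows. Terms annotated with more
  than 2500 genes, or with FDR at or above 0.001, are flagged rather than
  removed. Candidate gene sets are tested against uniformly drawn
  same-size sets; nulls matched for co-expression or mean expression are
  out of scope and the uniform null is known to be liberal in that
  respect.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `density` | 0.10 (sweep 0.10–0.30) | fraction of possible edges | sparse enough for modular structure, dense enough to stay well above the spanning tree |
| `gamma` | 2 | – | resolution yielding fine-grained modules on dense functional graphs; 1 exposed for robustness sweeps |
| `n_runs` | 100 | runs | consensus stabilizes well below this on clear structure |
| `tau` | 0.5 | co-classification frequency | majority agreement; standard consensus threshold |
| `scales` | {2, 3} | wavelet levels | 0.026–0.103 Hz at TR = 2.42 s, the conventional resting-state band |
| `n_components` | 3 | – | matches the three response metrics |
| `n_boot` | 1000 | draws | SE stability; 200 is adequate at test scale |
| `n_perm` | 1000 | permutations | minimum attainable p of ~0.001 |

On the wavelet band: the dyadic band of scale `s` at sampling interval TR
is `[1/(2^(s+1) TR), 1/(2^s TR)]` Hz. At TR = 2.42 s, scales 2–3 span
0.0258–0.1033 Hz. Figures of 0.111 Hz sometimes quoted for this band are
not reproducible from the dyadic formula at that TR; `scale_band()` reports
the dyadic values.

## Numerical conventions

* **Edge superimposition ties** are broken by lexicographic region order;
  edges are added in order of decreasing *signed* correlation, so negative
  correlations are only ever used after all positive ones.
* **Edge-count rounding** is half-away-from-zero; a density implying fewer
  than `n - 1` edges returns the MST with a recorded warning.
* **Component sign orientation**: each component is flipped so its
  strongest score-response correlation is positive, ties broken by
  response column order (k_intra, k_inter, d). For a component aligned
  with a pure planted pattern the k_intra and d correlations have exactly
  equal magnitude, so which variable wins is decided by noise; analyses
  that compare against planted ground truth therefore align signs to the
  truth first. Reported |r| values are orientation-invariant.
* **Isolated nodes** (degree 0) get `NA` participation coefficient and
  distance and are listed in an attribute rather than dropped silently.
* **Zero-variance genes** are removed before Z-scoring (the transform is
  undefined); the count is recorded.
* **Outlier regions**: the criterion is a mean inter-regional expression
  correlation below `median - 3 IQR` across regions. The rule is a
  documented stand-in — scale-free, robust, one threshold — and flagging
  more than 20% of regions is treated as an upstream mismatch error
  rather than an exclusion.
* **Region-sample matching** takes, per donor, the single nearest sample
  to the region centroid and to its x-mirrored image (pooling homologous
  regions across hemispheres), averaging the selections; ties go to the
  earlier sample. A within-radius averaging option exists.
* **Consensus non-convergence** after 20 iterations is an error carrying
  the final co-classification matrix.

## What the synthetic generator emulates

The generator is the package's study system, and its defaults are the
study conditions: 200 regions in 8 modules, 10 subjects of 256 timepoints
at TR = 2.42 s, 5000 genes, two planted expression components at
per-gene signal-to-noise 2.

* **Space**: modules are isotropic Gaussian clusters (s.d. 10 mm) around
  centres separated by at least ~45 mm in a 150 mm box — the simplest
  embedding that yields the empirical confound between distance and
  modularity (inter-modular edges are physically longer). The spatial
  clusters double as contiguous block labels for the block permutation.
* **Dynamics**: region signals mix a module factor (weight `p_in`), a
  global factor (`p_out`), a distance-decaying local coupling field, and
  unit noise; designated hubs additionally load on every other module's
  factor. Each region's structured signal is scaled by a per-region
  coupling amplitude drawn once from U(0.4, 1.6), emulating the broad
  degree distributions of real functional networks; without it, intra- and
  inter-modular degree anti-correlate mechanically under the fixed edge
  budget, which real hub-rich networks do not show.
* **Expression**: component 1 follows the standardized contrast
  `z(k_intra) - z(d)`, component 2 follows `z(k_inter) + z(d)`, computed
  from the realized network's own metrics. Planted gene weights are
  non-negative (U(0.5, 1.5) on the signal genes): each planted program is
  a coherently co-upregulated gene set, so its genes rank at one end of
  the weight list. Component amplitudes are `effect_size * (1, 0.3)` —
  the leading transcriptional gradient dominates. Noise is a unit-variance
  Gaussian random field built by distance-kernel mixing of white noise
  (autocorrelation length 20 mm).
* **Annotations**: two planted terms per component drawn from that
  component's signal genes, background terms uniform over the genome.

**Identifiability, and what passing tests do and do not show.** A planted
component carried by K of p genes over n regions cannot be recovered by any
linear weight estimate beyond `|r| = sqrt(nK / (nK + p - K))` — with
K = 100 of 5000 genes and n = 200 that ceiling is 0.896 at any signal
strength, which motivates the broad default of K = 1000. Two further caps
are structural: the two planted regional patterns share the distance term
with opposite signs, so they are strongly anti-correlated (about -0.5 to
-0.6 in realized networks), and PLS extracts orthogonal components that
must mix such oblique patterns; and gene-wise Z-scoring saturates per-gene
correlations at `a/sqrt(1+a^2)` for per-gene amplitude `a`, limiting how
much amplitude asymmetry can separate them. The measured recovery at the
default conditions is therefore around 0.8–0.85 for component 1 and
0.65–0.8 for component 2 (`scripts/acceptance.R` recomputes these), while
the qualitative structure — distinct component-to-truth matching and the
sign pattern (+k_intra, -d; +k_inter, +d) — is recovered reliably. Passing
tests show the pipeline recovers planted structure up to these information
limits; they do not show that real cortical expression gradients decompose
this way, and the generator does not model donor-level microarray noise,
hemodynamics, head motion, or cell-type composition.

## Problem sizes in the test suite

Unit tests run on 40–120-region networks with a few hundred genes; the
end-to-end property checks use the full default conditions (200 regions,
5000 genes) with 100-run consensus, 200 bootstrap draws, and 200-simulation
permutation calibrations at 199 permutations each — sizes chosen so the
properties under test (oracle agreement, calibration within binomial error,
planted-structure recovery) are measured with adequate power while the
whole suite stays fast enough to run routinely.

## Known limitations

* The enrichment null draws candidate sets uniformly; correlated gene sets
  make it liberal.
* The block permutation uses the generator's (or k-means) blocks; it
  mitigates, but does not remove, spatial-autocorrelation inflation — in
  the strong-autocorrelation calibration both schemes reject a planted
  null too often, with the block scheme markedly less so.
* Weighted-graph modularity, overlapping communities, negative-weight
  network analysis and sparse/regularized PLS are out of scope.
* The small-world sigma uses a random-graph clustering reference, not a
  lattice reference.
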