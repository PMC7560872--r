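---
title: "Identifying metastable community states with mapperstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying metastable community states with mapperstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapperstates)
```

## The model

`mapperstates` treats a microbial time series as a point cloud in a
compositional phase space. Each sample is a probability distribution over
taxa; the density of samples in a region of phase space is read as an
(inverse) potential: regions the community occupies often and persistently
are candidate metastable states, and the dynamics are coarse-grained into
stochastic transitions between those states. The pipeline makes no
mechanistic assumptions — no interaction network, no population-dynamics
model, no preset number of clusters — and uses only the pairwise distance
structure of the observed compositions.

The assumptions that *are* made:

* relative abundances adequately represent the community (absolute
  abundance information is not used, though the machinery would accept it);
* the sampling frequency resolves the dynamics of interest — states that
  the system enters and leaves between consecutive samples are invisible;
* the density of sampled points tracks occupancy: heavily perturbed or
  strongly non-stationary series violate this reading and the "states" are
  then descriptive rather than dynamical.

## Phase-space metric

Compositions are compared with the square root of the Jensen–Shannon
divergence. We fix base-2 logarithms so that distances live in [0, 1]
(disjoint supports are exactly distance 1); the base is a free convention
and does not change any ranking, cover, or state because every downstream
step is invariant under a global rescaling of the metric. sqrt-JSD is a
true metric (the triangle inequality is property-tested in the suite), is
defined for zero-containing compositions without pseudocounts, and is
bounded — all convenient for rank-based filters.

The Aitchison distance (Euclidean after centered-log-ratio transform) is
provided as an alternative. It requires strictly positive entries; by
default a zero entry is a hard error, and an optional multiplicative
pseudocount (0.5 × the smallest nonzero relative abundance, or a
user-supplied value) can be enabled explicitly. We do not silently impute:
zero handling changes the geometry and must be the user's decision.

Taxa observed in no sample are dropped before distance computation; they
contribute nothing to either metric.

## The Mapper graph

The graph construction follows the classical Mapper recipe with two
rank-PCoA filters:

1. **Filter.** Classical MDS (PCoA) of the distance matrix: Gower-center
   −d²/2, eigendecompose, keep the top two components scaled by the square
   roots of their eigenvalues. sqrt-JSD matrices are generally
   non-Euclidean, so negative eigenvalues are discarded; the embedding is
   the best positive-semidefinite rank-2 approximation. Signs are fixed by
   making the largest-magnitude loading of each component positive, so
   runs are deterministic. The two coordinates are then replaced by their
   ordinal ranks (ties broken by input order). Ranking uniformizes the
   filter marginals, which makes equal-width bins carry comparable
   occupancy; the loss of geometry is harmless because all clustering
   happens on the *original* distances.
2. **Cover.** Per dimension, `n_intervals` closed intervals of equal
   length L span the observed rank range, consecutive starts spaced
   L·(1 − overlap/100), the last interval clamped at the maximum; solving
   for L gives L = span / (1 + (n − 1)(1 − overlap/100)), i.e. exactly
   `n_intervals` intervals. 2-D bins are the Cartesian product; a sample
   joins every bin containing its rank pair; empty bins are dropped. The
   interval-boundary convention (closed, range-clamped) is one of several
   in circulation; it is documented here and fixed, and with overlap
   < 50 % a sample can belong to at most 4 bins.
3. **Local clustering.** Within each bin, single linkage on the bin's
   sub-matrix of distances. The dendrogram merge heights are histogrammed
   into `n_hist_bins` (default 10) equal-width bins spanning
   [0, max within-bin distance]; the cutoff is the lower edge of the first
   *empty* histogram bin that follows a non-empty one. This implements
   "separation of length scales": small within-cluster merges populate the
   low bins, the between-cluster merge sits high, and the first gap
   between them is the scale split. If no such gap exists — including the
   degenerate all-equal-distances case — there is no evidence of scale
   separation and the bin stays a single cluster. Bins with fewer than 3
   members carry at most one merge height and cannot exhibit a gap, so
   they also form one cluster. (A strictly literal "first empty bin"
   rule, counting the leading empty bins below the smallest merge height,
   would cut at height 0 and shatter exactly the bins that are most
   clearly single clusters; we regard that reading as a defect and use
   the gap rule.)
4. **Nerve.** One vertex per local cluster; an edge joins two vertices iff
   they share at least one sample. No self-loops, no multi-edges.

Graph layout (Fruchterman–Reingold) is seed-controlled and strictly
presentation-level; nothing in the analysis or the tests depends on it.

### Hyperparameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_intervals` | cover resolution per filter dimension | (10, 10) | published analyses use 15–30 per dimension at data sizes of hundreds of samples |
| `overlap_pct` | percent overlap of consecutive intervals | 50 | 50–70 in published analyses; higher overlap = more shared members = better-connected graphs |
| `n_hist_bins` | histogram bins for the clustering cutoff | 10 | the conventional default |
| `k` | kNN neighbourhood for density | 10 % of n, rounded | fixed convention; see below |

The published rule of thumb for choosing the cover — the largest vertex
should hold at most ≈10 % of the samples, and singleton components should
be minimized — is implemented as `check_hyperparameters()` and reported on
every pipeline run, but it is advisory: it never mutates the graph.

The benchmark configuration used in the acceptance suite is **coarser**
than that rule suggests: (8, 8) intervals at 70 % overlap for the
synthetic recovery worlds. The synthetic generators produce a small number
of compact, strongly separated Dirichlet modes of ~100 samples each; a
cover fine enough to satisfy the 10 %-largest-vertex rule slices each mode
into many vertices whose occupancy fluctuates, creating spurious local
density maxima that split one true mode into several states. The rule
targets *resolution discovery* in rich real data sets with unknown
substructure; when the feature scale is known (as it is by construction in
a simulation benchmark), the cover should match it — about one bin per
half-mode. Neighbouring coarse settings behave the same way, so this is a
regime choice, not a tuned point.

## Density, maxima and state assignment

For sample i, kNN(i, k) is the mean distance to its k nearest other
samples (ties at the k-th neighbour broken by sample index, so exactly k
neighbours enter and the estimator is deterministic). For a vertex V with
n members,

D_inv(V) = Σ_{i∈V} kNN(i, k) / n²,  D(V) = 1 / D_inv(V).

One factor of n averages the members' kNN distances; the second rewards
vertex occupancy, compensating for the differing numbers of points
aggregated per vertex. k defaults to 10 % of the number of samples
(rounded, minimum 1), computed over the pooled data set. Doubling all
distances halves D — only density *ratios* matter, and the suite verifies
that every downstream result is invariant under strictly increasing
transformations of D.

A vertex is a local maximum iff no neighbour has higher density and any
equal-density neighbours belong to a plateau none of whose members has a
higher neighbour; each vertex of such a plateau is a maximum, and maxima
connected through maxima-only undirected paths are merged into one state.
Isolated vertices are maxima. Edges are oriented toward higher density;
equal-density edges become a pair of opposite arcs so plateaus remain
mutually reachable. Each non-maximum vertex is assigned to the state whose
maxima set it reaches by a *uniquely* shortest directed path (hop count);
vertices equidistant to two or more states, or unable to reach any maximum
under the orientation (possible, and logged), are `unassigned` — the
transition regions between basins.

Degenerate case: a vertex whose members are mutual duplicates has
D_inv = 0; its density is recorded as `Inf` with a warning. Real data sets
do not produce this; exact duplicate samples do.

A sample inherits the union of the state labels of every vertex containing
it (overlapping bins mean a sample can sit in several vertices); samples
carrying several labels are read as lying near the saddle between states.
`sample_majority_state()` collapses the label set to the most frequent
label for benchmarking only.

## Temporal correlation

For a subject's time-ordered label sets, p(t) is the number of distinct
labels at time t (`unassigned` counts as one label) and
f′_x(t) = f_x(t)/p(t) ∈ {1, 1/2, 1/3, …}. For state x, every ordered pair
of sample times (t, t + τ) with x among the labels at t contributes the
raw value f′_x(t + τ); τ is the *exact* empirical time difference
(irregular sampling is first-class; no gridding), and τ = 0 pairs each
sample with itself. corr_x(τ) is the per-τ mean; the SEM uses the unbiased
standard deviation and is undefined (NA) for single-pair τ. Start
qualification uses membership only — the 1/p weight applies at the end of
the interval, not the start.

Smoothing, when requested, is a transparent moving average of the per-τ
means over a window of ± bandwidth/2; the raw pairs are never modified.
The reference analyses smooth their published curves with an unstated
method, so we chose the simplest defensible smoother rather than guessing
at fidelity. `monotonicity_index()` (Spearman correlation of mean vs τ)
operationalizes the qualitative reading: ≈ −1 means monotone decay
(transient occupancy), values near or above 0 mean recurrence.

A statistical caveat that the acceptance suite respects: raw pairs from a
single chain overlap in time and are positively dependent, so the per-τ
SEM understates the sampling error of corr_x(τ). Comparisons against
chain theory are therefore made across independent replicate chains (one
corr estimate per subject, SEM across subjects).

## Rarefaction robustness

`robustness_run()` draws random subsets (default 90/50/10 %, 10 replicates
each, round-half-away-from-zero subset sizes, minimum 3), subsets the
precomputed distance matrix (distances are per-pair, so subsetting and
recomputing commute — property-tested), re-runs Mapper with the unchanged
base hyperparameters, and summarizes: per-vertex dominant-feature fraction,
and within- vs between-group edge density, where a vertex's group is its
dominant feature class and edge density between groups A and B is observed
A–B edges over possible A–B vertex pairs. The published readout is a
shaded circular layout; the numeric within/between summary is the testable
surface, and the layout remains presentation-only. Density estimation and
state assignment are deliberately not re-run on rarefied subsets — the
test targets the robustness of the graph structuring, and k is not
rescaled. Numeric grouping features (depth-like) are quartile-binned.

## Synthetic worlds

Two generators provide ground truth:

* `simulate_antagonistic()` — a two-species bistable toy: a latent
  dominance variable follows a discrete-time double-well diffusion
  z ← z + a·z(1 − z²)·Δt + σ√Δt·ε, each sample an independent short run
  from a uniform start; X and Y split the focal mass (1 ± z)/2 and a few
  bystander taxa carry log-normal noise. Defaults (a = 4, σ = 0.25, 200
  samples, focal mass 0.8) put essentially all probability near the two
  wells, with balanced mode occupancy from the uniform start; a = 0 is the
  null control with no bimodality. The *density shape* — two heavy modes
  joined by a sparse corridor — is the contract; the specific dynamics are
  not, and nothing downstream depends on them.
* `simulate_markov_community()` — per subject, a Markov chain over S
  compositional states; each time point draws from the current state's
  Dirichlet (mean = the state's characteristic composition, concentration
  = within-state tightness). Defaults: S = 3 over 9 taxa with block-mass
  0.8 means (pairwise JS separation > 0.5, enforced), concentration 50,
  stay probability 0.9, one subject, 300 time points. These are the sample
  sizes and separations the recovery benchmark states; the stay
  probability matches the value used in the chain-theory checks.

What the generators do *not* emulate: compositional zeros and sequencing
sparsity, taxon-count dimensionality in the thousands, autocorrelated
within-state drift, uneven sampling intervals, and measurement noise
models. A green recovery test therefore establishes that the pipeline's
machinery is correct and that well-separated metastable structure is
recoverable — not that any real data set has such structure, nor that the
method resolves weakly separated states at realistic noise levels.

All randomness descends from user-supplied integer seeds; rarefaction
derives one sub-stream per (fraction, replicate) from the master seed and
restores the caller's RNG state.

## Numerical choices

* JSD is computed as H(m) − (H(p)+H(q))/2 in bits, with 0·log 0 = 0 and a
  clamp of tiny negative round-off before the square root.
* PCoA discards eigenvalues below max(λ)·1e-12 as numerically zero; with
  fewer positive eigenvalues than requested components, the available ones
  are returned with a warning (and a single component is duplicated for
  the 2-D cover in the degenerate 1-D case).
* Rank ties break by input order (ordinal ranks) — deterministic, no
  fractional ranks.
* kNN ties at the k-th neighbour break by lower sample index.
* Equidistance in state assignment is exact integer hop-count equality, so
  no floating-point tolerance is involved.
* Subset sizes in rarefaction round half away from zero.

## Limitations

* Mapper hyperparameters remain heuristic; the largest-vertex rule is
  advisory and conflicts with blob recovery at small scales (see above).
  No automatic optimization is attempted.
* States are defined by sampled density: undersampled basins merge or
  vanish, and strongly non-stationary series produce states that reflect
  sampling history rather than dynamics.
* The temporal correlation function is descriptive; no Markov model is
  fitted and no stability classification is automated.
* 16S read processing, OTU construction and taxonomy are out of scope: the
  pipeline starts from an abundance table.
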