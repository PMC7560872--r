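# mapperstates

Metastable community states and state transitions in microbiome time
series, via topological data analysis.

## The problem

Microbial communities (gut microbiomes, marine picoplankton, ...) are
high-dimensional and noisy, yet large-scale phenotypes — disease versus
recovery, seasonal water-column mixing — persist far longer than the
fluctuations of individual taxa. A productive coarse-graining treats each
sample as a point in a compositional *phase space* and asks where the data
density has local maxima: regions of phase space that the community
occupies persistently behave like basins of a potential landscape, i.e.
**metastable states**, and the dynamics become stochastic transitions
between them.

`mapperstates` implements that pipeline for sample × taxon relative
abundance tables:

1. **Phase-space metric** — compositions are treated as probability
   distributions and compared with the square root of the Jensen–Shannon
   divergence, d(p,q) = √JSD(p,q) (base-2 logs, so d ∈ [0,1]); the
   Aitchison (clr-Euclidean) distance is available as an alternative.
2. **Mapper graph** — the point cloud's shape is summarized as an
   undirected graph: classical-MDS (PCoA) coordinates are rank-transformed
   into two filter values, the rank plane is covered by overlapping 2-D
   bins, each bin is clustered by single linkage with a
   first-empty-histogram-bin cutoff, and each local cluster becomes a
   vertex, with an edge whenever two vertices share a sample.
3. **Density and states** — per-vertex density D(V) = n² / Σ_{i∈V} kNN(i,k)
   with kNN(i,k) the mean distance to the k nearest samples (k = 10 % of
   the data set). Edges are oriented toward higher density; each vertex is
   assigned to the basin of the local density maximum it reaches by a
   uniquely shortest directed path, and vertices equidistant to several
   maxima are flagged `unassigned` (transition regions).
4. **Dynamics** — the temporal correlation corr_x(τ) = ⟨f′_x(t+τ)⟩ over
   all sampled intervals starting in state x, with f′_x = f_x / p
   down-weighting samples associated with p states at once. Monotone decay
   indicates transient occupancy; non-monotone curves indicate recurrence.
5. **Robustness** — rarefaction re-runs Mapper on random 90/50/10 % subsets
   and summarizes within- vs between-group edge densities for a chosen
   sample feature.
6. **Synthetic ground truth** — an antagonistic two-species toy ecosystem
   and a Markov–Dirichlet multi-state simulator make every stage testable
   without external data.

## Worked example

```r
library(mapperstates)

sim <- simulate_markov_community(S = 3, n_timepoints = 120, seed = 42)
tab <- to_relative_abundance(sim$table)
D   <- pairwise_distances(tab, metric = "js")
round(D[1:3, 1:3], 3)
#>       s0001 s0002 s0003
#> s0001 0.000 0.280 0.731
#> s0002 0.280 0.000 0.636
#> s0003 0.731 0.636 0.000

g  <- run_mapper(D, mapper_config(c(8, 8), overlap_pct = 70))
g
#> mapper_graph: 108 vertices, 756 edges, 120 samples covered

ps <- partition_states(g, D)           # density, maxima, basins
ps$partition
#> state_partition: 3 state(s), 0 unassigned vertex/vertices of 108

maj <- sample_majority_state(g, ps$partition)[tab$samples]
adjusted_rand_index(maj, sim$truth)
#> [1] 1
```

The three Dirichlet modes of the simulator are recovered exactly: the
Mapper graph splits into three lobes, each with one density maximum, and
every sample's majority state matches its generating state (adjusted Rand
index 1). State persistence is then quantified by the temporal correlation
function:

```r
lab <- sample_states(g, ps$partition)
s   <- membership_series(lab, tab$meta, "subj1")
cs  <- temporal_correlation(s, "1")
head(cs$summary, 5)
#>   tau n_pairs      mean        sem
#> 1   0      60 1.0000000 0.00000000
#> 2   1      60 0.9000000 0.03905667
#> 3   2      60 0.8333333 0.04851854
#> 4   3      60 0.8000000 0.05207556
#> 5   4      60 0.7833333 0.05363439
```

corr(1) ≈ 0.90 recovers the chain's stay probability of 0.9, and the slow
decay toward the stationary occupancy is the signature of a metastable
state. `plot(cs, bandwidth = 2)` draws the dots/line/ribbon view;
`plot(g, color = ps$partition$state_of)` draws the state-coloured graph
(force-directed layout is presentation-only — rely on connectivity, not
shape).

A file-based run (TSV in, TSV/GraphML/JSON artifacts out) goes through
`pipeline_config()` + `run_pipeline()`, or the command line:

```sh
Rscript -e 'mapperstates::mapper_cli()' simulate --kind markov --n 120 --out data/
Rscript -e 'mapperstates::mapper_cli()' run --config conf.txt
```

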