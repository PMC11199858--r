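---
title: "Methods: weight renormalisation, map-equation modules, hub roles and temporal tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weight renormalisation, map-equation modules, hub roles and temporal tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexflow)
```

# The problem

Mesoscale connectomes from retrograde tracing report, for every injected
(target) area, how many labelled neurons each source area contains. The
conventional normalisation divides each target's counts by their total,
giving the fraction of labelled neurons extrinsic (FLNe): every measured
column of the weight matrix sums to 1. That removes between-target
differences in total in-weight — the weighted in-degree of every connected
area becomes exactly 1 — and so discards part of the signal that network
analysis needs. When the per-experiment totals (LNe) are available, the
absolute in-link weights can be recovered by rescaling each column back up,
and the analysis can run on a weight matrix whose entries are labelled-neuron
counts spanning several orders of magnitude.

`cortexflow` implements that renormalisation and the analyses downstream of
it: degree/strength statistics, weight–distance decay fits, modular
decomposition of the directed weighted network by the map equation, hub and
connector classification by the z–P role cartography, probability-flow link
ranking, and time-evolving link tracing around seed areas. A synthetic
connectome generator with known ground truth makes every stage testable
without any external download.

# Weight representations

A `connectome` holds a node table and a non-negative matrix `W[s, t]`
(rows = sources, columns = targets, zero diagonal) tagged `"FLNe"` or
`"LNe"`. The two conversions are exact inverses given matched injection
records:

* `lne_to_flne()` divides each non-zero column by its sum;
* `flne_to_lne()` multiplies each measured column by that target's combined
  labelled-neuron total, so `sum_s LNe(s, t) = LNe(t)`.

Repeated injections at one target are pooled with the arithmetic **mean** of
their LNe totals by default. The mean is stable when targets have unequal
repeat counts; `sum` (pools all experiments into one effective injection)
and `max` are selectable. Unmeasured areas keep all-zero in-columns
throughout; censoring is a property of the data, not of the analysis.

Inter-area distances are Euclidean distances between area centroids in mm.
Along-cortex geodesics would be longer, especially across sulci, but need a
surface mesh; the straight-line metric is reproducible from coordinates
alone and is used consistently in the decay fits and the tracing stage.

# Graph statistics

Degrees count non-zero links; strengths sum weights. Distribution families
(exponential, normal, log-normal) are fitted by closed-form maximum
likelihood and ranked by bare total log likelihood — no AIC/BIC penalty,
since the families compared carry essentially the same complexity and the
comparison mirrors common practice for these data. Zero weights are absent
links, never samples; they are excluded from log-scale fits with their count
reported.

Weight–distance decay is fitted by unbinned ordinary least squares in the
transformed space: `ln w ~ d` for the exponential model (decay length
`lambda = -1/slope`, mm) and `ln w ~ ln d` for the power law
(`gamma = -slope`). `r_squared` is reported in that log space, where the
fits are linear. Binning by distance before regression would weight the
sparse long-distance tail differently; unbinned per-link OLS is the simplest
reproducible convention and recovers generator decay lengths to ~1% at
moderate noise (see the parameter-recovery tests).

# Random-walk flow and the map equation

The walker follows out-links proportionally to weight with probability
`1 - tau` and teleports uniformly otherwise; dangling nodes teleport with
probability 1. The default `tau = 0.15` is the standard teleportation rate
that guarantees ergodicity on censored, weakly connected matrices. The
stationary visit rates solve the PageRank-style fixed point; the package
carries two independent solvers (power iteration to residual < 1e-12, and a
direct linear solve) that agree to ~1e-12 and cross-check each other in the
tests. Link flow is `f(s, t) = (1 - tau) p_s W[s, t] / s_out(s)`.

A two-level partition M is scored by the map-equation codelength

    L(M) = q H(Q) + sum_m p_m H(P_m)   [bits],

with module exit rates `q_m` (boundary-crossing link flow plus the
teleportation share landing outside the module; teleportation steps are
encoded — the recorded-teleportation convention), `q = sum_m q_m`, and
per-module codebooks over node visit rates plus the exit symbol. With all
nodes in one module, L reduces to the entropy of the visit rates.

`optimize_partition()` minimises L by greedy single-node moves (each node
tried against its neighbours' modules, shuffled order) alternating with a
module-merge phase, restarted `n_trials` times (default 100) from
all-singleton states; the best restart wins and the whole search is
deterministic given its seed. On graphs small enough for exhaustive
enumeration over all set partitions (n <= 8, Bell(8) = 4140) the greedy
optimum equals the global minimum in >= 95% of random instances. Only the
flat two-level code is implemented: the analyses this package supports
report flat module lists, and the hierarchical code adds machinery without
changing them. Areas with no links at all carry no structural flow and are
excluded as orphans before the walk is set up, then reported separately with
zero module flow. Module ids are renumbered by descending module flow, so
module 1 always carries the most traffic.

Louvain modularity maximisation (via igraph, on the symmetrised matrix
`(W + W')/2`) is the independent comparison method. `modularity_q()`
defaults to the undirected variant for the same reason — it is what a stock
Louvain implementation with default settings optimises on a directed matrix
— with the directed variant available. Q is invariant under global weight
rescaling, as is the map-equation partition (flows are ratios).

# Hub roles

For a partition and a direction (in or out), each area gets

* a participation coefficient `P_i = 1 - sum_m (s_im / s_i)^2`, and
* a within-module z-score `z_i = (kappa_i - mu_m) / sigma_m`,

computed from **weighted** degrees by default — the entire analysis is
weight-driven, and binarised variants are retained only for comparison with
unweighted studies. `sigma_m` is the population standard deviation,
following the original role-cartography convention; `sigma_m = 0` modules
(singletons, uniform kappa) give z = 0 rather than an error. Note that a
single outlier among `n_m` module members cannot exceed
`z = sqrt(n_m - 1)`, so hubs are only detectable in modules of at least 8
members under the default cutoff.

Roles follow the z–P cartography: hubs have `z > 2.5` (R5 provincial at
`P <= 0.30`, R6 connector at `P <= 0.75`, R7 kinless above); non-hubs split
at `P = 0.05 / 0.62 / 0.80` into R1, R2, R3 (non-hub connector) and R4
(kinless). Those constants were tuned on cellular metabolic networks and may
need revisiting for cortical networks, so they are configuration values
(`role_boundaries()`), and the band `2 < z <= 2.5` is flagged *marginal hub*
rather than discarded. Hub lists rank by z, connector lists by P, each over
the union of directions.

# Temporal tracing

Assuming a constant conduction velocity (default 1 m/s, i.e. 1 mm/ms,
typical of unmyelinated local axons), link length maps to latency, and a
fixed synaptic delay (default 2 ms, equivalent to 2 mm of extra path) is
added per relay. `trace_links()` activates the first-neighbour shell of the
seeds, then the second shell, recording per link the earliest arrival
(`path length / velocity + (order - 1) * delay`) and keeping each node's
earliest arrival when several paths reach it — the physically meaningful
de-duplication for a latency analysis. Display defaults keep links of
weight > 1 and length < 5 mm, the regime where labelled-neuron counts are
clearly interpretable and clusters are local; both cutoffs are plain
parameters and longer pathways are followed by raising `max_length_mm`.
Arrival times are validated against an independent bounded-hop
earliest-arrival search in the tests, and scale inversely with velocity
(delays fixed).

# The synthetic generator

`generate_connectome()` emulates the statistical structure the analyses
assume, with known ground truth:

* ~116 areas in a 25 x 15 x 10 mm box; 8 planted modules whose centres are
  placed by farthest-point selection from a uniform candidate pool (mutual
  separations come out around 9 mm) and whose members scatter around them
  with a 2 mm Gaussian — modules are spatially compact, as cortical modules
  are anatomically local, and the separation keeps distinct modules from
  collapsing onto each other in the small volume;
* directed links with probability `p_within = 0.95` inside and
  `p_between = 0.5` between planted modules — chosen so the censored
  network carries on the order of 3,500 links (~55% of the observable
  source-target pairs), matching the density regime of the real resource;
* weights `weight_scale * exp(-d / lambda) * exp(N(0, log_sigma^2))` with
  `lambda = 4.57` mm (the decay length reported for the real data),
  `weight_scale = 1000` and `log_sigma = 1` so that censored weights span
  roughly five to six orders of magnitude like the rescaled labelled-neuron
  counts;
* censoring of in-links to a random subset of 55 "injection sites"
  (`censor()`), which reproduces the characteristic in/out degree asymmetry
  (out-degree is capped by the number of measured targets).

One RNG stream per `generate_connectome()` call makes output a pure
function of the seed. `to_flne()` produces the matched FLNe view plus
injection records whose totals equal the column sums, so the
renormalisation round trip is exact by construction and is tested to 1e-9.

What the generator does **not** emulate: biological neuron-count
distributions, laminar or hemispheric structure, geodesic (rather than
straight-line) link lengths, and the expert, non-random choice of injection
sites in real experiments. Passing tests therefore demonstrate the
correctness and statistical behaviour of the algorithms under the stated
generative assumptions, not anatomical conclusions about any species.

## Benchmark regimes used in the tests

Two deliberate parameter regimes appear in the test-suite and the
reproduction script:

* *Planted-module recovery* runs at `p_within = 0.6, p_between = 0.05,
  K = 4, n = 60` with `log_sigma = 0.5`. Strong topological separation with
  moderate weight noise is the regime where the planted partition is the
  information-theoretic optimum; at the generator's default noise
  (`log_sigma = 1`+) individual link weights vary enough that the
  minimum-codelength partition can legitimately differ from the planted one
  for a few border nodes, which is a property of the map equation, not an
  optimiser failure.
* *Decay-length recovery* also uses `log_sigma = 0.5`; the fitted
  `lambda` then lands within 10% (empirically ~1%) of the generating value
  over 20 seeds.

# Numerical choices

* Power iteration converges to `max |dp| < 1e-14` (well under the 1e-12
  stationarity residual the analyses assume); the iteration cap (10,000)
  only triggers on pathological input and raises an error rather than
  returning a stale vector.
* Codelength bookkeeping clamps tiny negative exit flows (float noise from
  incremental updates) at zero; `0 log 0 = 0` throughout.
* Greedy moves accept only improvements below `-1e-13` bits, making the
  optimiser insensitive to tie-breaking noise; restarts use shuffled node
  orders drawn from the user seed.
* `top_flow_links(fraction = f)` keeps `floor(f * n_links)` links after
  sorting by flow with (source, target) label tie-breaks, so rankings are
  deterministic.
* Degenerate inputs are errors, not NaNs: empty link lists, zero-variance
  samples in family fits, all-equal distances in decay fits, measured
  targets without injection records.

# Problem sizes

The shipped analysis scripts and tests run at the scale the package
targets: 116 areas, ~3,500 links, 100 optimiser restarts. Exhaustive
map-equation enumeration is used up to n = 8 (4,140 partitions); recovery
benchmarks use 20 seeds at n = 60–116. A full pipeline run at this scale
takes on the order of a minute on one core.

# Known limitations

* The map equation is two-level only; very deep modular hierarchies would
  be summarised at their top level.
* Louvain is delegated to igraph and inherits its tie-breaking; only the
  seed-controlled reproducibility of the best-of-restarts result is
  guaranteed.
* The censoring model zeroes whole columns; it does not model partial
  sampling within a column (e.g. undetected weak projections at measured
  sites).
* Distances are straight-line; tracing latencies through deeply folded
  cortex will be underestimated relative to along-fibre path lengths.
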