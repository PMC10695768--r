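---
title: "Models and methods behind msbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbnet)
```

`msbnet` studies multi-synaptic boutons (MSBs): presynaptic terminals of
CA3/2 axons that contact dendritic spines of several distinct CA1 neurons.
This vignette documents the models the package implements, the parameters
that matter, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## The network model

The feed-forward model has two populations of 100 neurons. CA3/2 sources
are independent homogeneous Poisson processes at 10 Hz. Each source owns 12
boutons, 5 projecting to the stratum oriens (SO, basal dendrites) and 7 to
the stratum radiatum (SR, apical dendrites). A bouton carries between 1 and
5 active zones; each active zone contacts one uniformly chosen CA1 neuron,
distinct within a bouton — one MSB therefore links one presynaptic spike to
several different cells.

Per-layer active-zone count distributions are only constrained by three
empirical facts: the SO MSB fraction is about 45%, SO boutons with more
than 3 contacts are about 15%, and the SR MSB fraction is about 25% with a
multi-contact shape proportional to the SO shape. The package's defaults,

```{r}
az_dist_so()
az_dist_sr()
```

satisfy those constraints exactly (P(2..5) sums to 0.45 with P(4)+P(5) =
0.15; SR rescales the SO multi-contact tail to 0.25). The per-count split
below 45% is a package choice — the source data constrain the tail sums,
not each count — and both distributions are arguments everywhere they are
used.

Three further per-bouton properties are drawn once and shared by all of a
bouton's active zones:

* **Release probability** p ~ Gamma(shape 2, scale 0.15), clipped at 1.
  Clipping (rather than resampling) is the literal reading of "bounded to a
  maximum of 1"; the clipped mass at 1 is ~1.7% so the two readings barely
  differ.
* **Short-term plasticity identity** (facilitating or depressing). The
  published fraction is unstated, so the default is an independent fair
  coin per bouton (`facil_fraction = 0.5`, configurable). The matched
  variant pairs high-p boutons with depression and low-p boutons with
  facilitation; the cut point is also unstated and defaults to the median
  of the drawn p values, which keeps the two classes balanced.
* Within-bouton targets are drawn **without replacement**. The source text
  only says "randomly chosen", but the phenomenon being modeled is one
  bouton contacting *different* neurons, so distinct targets are the
  faithful reading. With 5 targets among 100 neurons the distinction is
  minor in any case.

Single-mechanism variants isolate the three candidate routes by which MSBs
could synchronise CA1: `multiplicative_only` keeps the stratified wiring
but fixes p = 1 with no plasticity (pure spike copying);
`release_only` and `stp_only` replace the 12-bouton layout with either 5
single-AZ boutons or 1 five-AZ bouton per source, so total synapse count is
matched and only the *sharing* of stochastic release (or of the plasticity
state) differs between the SSB and MSB scenarios.

## Neuron, synapse and noise dynamics

CA1 neurons are current-based leaky integrate-and-fire units,

$$\tau_m \frac{dV}{dt} = -V + R\,(I_b + I_{syn}),$$

with τ~m~ = 60 ms, R = 1 GΩ, threshold 20 mV, reset 10 mV and a 2 ms
refractory period during which V is clamped. Without plasticity each
transmitted spike injects an exponential postsynaptic current of peak
200 pA decaying with τ~syn~ = 1.5 ms. Plastic synapses follow the
Tsodyks–Markram three-state resource model: fractions x (recovered), y
(active) and z (inactive) with x + y + z = 1, utilisation u. At a
transmitted spike u is updated first, u ← u + U(1 − u), then the release
u·x moves from x to y; the synapse contributes A·y(t) to its target's
current. Presets: facilitating A = 1540 pA, U = 0.03, τ~rec~ = 130 ms,
τ~fac~ = 530 ms; depressing A = 250 pA, U = 0.5, τ~rec~ = 800 ms,
τ~fac~ = 0 (u is simply U at every spike). The update order (u before
release) follows the canonical formulation; the delta-function notation of
the differential form is ambiguous on this point.

Numerical scheme. Integration is clock-driven at a fixed dt (default
0.1 ms) with **exact exponential propagators**: between events every state
variable evolves by the closed-form solution of its linear ODE, so a single
PSC is reproduced at machine precision at step boundaries and the
constant-current firing period matches the closed form
T = t~ref~ + τ~m~ ln((RI − V~reset~)/(RI − V~th~)) to within one step.
Forward-Euler stepping is deliberately not used. Per-active-zone resource
states are updated lazily, only at that zone's transmission events, using
the closed-form inter-event solution; because every synapse type shares
τ~syn~, per-target currents superpose into a single exponential state per
neuron. The recovered fraction x is propagated through its own integral
(not as 1 − y − z), which makes the conservation x + y + z = 1 a genuine
floating-point test of the algebra; the suite checks it to 10⁻⁹ over 10⁵
events.

Three dynamics details are unstated in the source description and fixed
here as defaults: the background Gaussian current (mean 12 pA, SD 20 pA)
is redrawn per neuron every 1 ms and held constant in between (the common
simulator convention; documented as dt-sensitive); synaptic transmission
delay is a uniform 1 ms; initial conditions are V(0) = 0 with fresh
resource states, and the first second of every run is discarded by the
analysis window, absorbing the transient.

Stochastic release is Bernoulli thinning of the bouton's source train,
performed independently per active zone with the bouton's shared p —
active zones of one bouton share the *parameter* and the plasticity
*identity*, but each has its own release realisation and its own resource
trajectory. Reading the statement "the plasticity state of a bouton
applies to all its active zones" as shared identity rather than a shared
trajectory is a deliberate choice: the zones see different transmitted
trains, so a literally shared (x, y, z, u) would be ill-defined.

## The synchrony readout

Each run bins the last 50 s (of 51 s simulated) of every CA1 train into
20 ms half-open bins — 2500 bins — and computes Pearson's correlation for
each of the 4950 neuron pairs; μ~cc~ is the mean. Pairs in which either
train has zero variance have an undefined coefficient: they are excluded
and counted rather than imputed as 0, and a result with no defined pair is
flagged degenerate with μ~cc~ = NA. Bins are anchored at the window start.

`run_condition()` reseeds *everything* per run — connectivity, release
probabilities, plasticity assignment, source trains, noise — because the
runs are described as independent without stating what is redrawn; a
`fixed_graph` flag reuses one graph for sensitivity analysis. Per-run
seeds derive deterministically from one master seed, so results are exactly
reproducible.

The test suite exercises the grid at reduced scale: 11 s simulated, 10 s
analysed, 20 runs per condition (the reference scale is 51 s and 100 runs).
At that scale each MSB condition already exceeds its SSB counterpart in
mean μ~cc~ by many standard errors, for the full model and for each
isolated mechanism, so the reduced scale suffices for the qualitative
claims; absolute μ~cc~ values at reduced scale are slightly noisier but
unbiased, since the 1 s transient is discarded either way.

## Morphometric estimation statistics

The homogeneity analysis asks whether a synaptic measure (spine volume,
PSD area, active-zone area) varies less within one MSB than across
neighboring SSBs. Per-MSB variances use the unbiased (n − 1) estimator —
the denominator is unstated in the source, and with groups of 2–5 contacts
the biased estimator would shrink group-size-dependently. "Neighboring
SSBs" are grouped as consecutive single-AZ contacts along a dendrite,
ordered by position, with group sizes drawn to match the MSB contact-count
histogram of the same table (a fixed-size alternative is exposed);
leftover contacts are unused, and dendrites with fewer than two SSBs
contribute nothing.

The comparison reports:

* **Cliff's delta**, computed exactly via midranks
  (δ = 2U/(n₁n₂) − 1 with U the Mann–Whitney count); the tests verify it
  against brute-force pair enumeration up to 50×50 and its antisymmetry
  and monotone-transform invariance.
* A **two-sided permutation test** (default 5000 reshuffles) on the mean
  difference, with the add-one correction (1 + hits)/(n + 1) so p is never
  exactly 0. The mean difference, not the t statistic, is the default
  because the estimation-statistics tooling this analysis style follows
  permutes the mean difference; the t statistic is an option.
* A **BCa bootstrap interval** (default 5000 resamples) for the median or
  mean difference, resampling each group separately; z₀ from the bootstrap
  CDF at the observed statistic (midrank-tied), acceleration from the
  jackknife skewness over both samples. Degenerate bootstrap distributions
  fall back to the percentile interval with a warning. The suite checks
  the symmetric-case collapse onto the percentile interval and
  cross-checks against an independent implementation.
* **Ryan–Holm step-down levels** for families of m intervals: rank k gets
  level 1 − α/(m − k + 1), so the most extreme comparison carries the full
  Bonferroni correction; the dual p-value side is Holm's procedure via
  `stats::p.adjust`.

## Dendrite self-proximity

To judge whether one cell's dendrites could contribute two spines to the
same bouton, the tree is resampled at constant 0.5 µm arc-length spacing
(branch points and tips preserved), decomposed into maximal unbranched
segments, and each node counts the distinct *other* segments with a node
within 5 µm Euclidean distance. Node pairs closer than 5 µm *along the
tree* are excluded: sibling segments meeting at a branch point are
near-coincident in space there, and without the exclusion they register as
contacts that no bouton could actually bridge. The exclusion radius is a
parameter; its default equals the 5 µm proximity threshold's scale rather
than tracking the threshold, so tightening the Euclidean threshold does
not silently re-admit branch-point artifacts. Nodes are ordered by somatic
path distance and averaged in 10 equal-count bins.

## Synthetic generators: what they emulate, and what not

`generate_synapse_table()` plants the exact structure the variance
pipeline assumes: lognormal measures (synaptic sizes are right-skewed)
with a shared additive bouton-level log factor — within-bouton log-SD
σ~W~ = 0.3 and between-bouton σ~B~ = 0.6 by default, an intraclass
correlation of 0.8 — measure-to-measure correlation through a shared
per-contact latent, and bouton volume growing as α^0.8. The parameters are
recoverable: at large n the mean within-MSB log variance estimates σ~W~²
and the variance of bouton means estimates σ~B~² + σ~W~²/n̄, which the
suite verifies by method of moments. Setting σ~B~ = 0 removes the shared
factor entirely, making within-bouton spread equal to across-bouton
spread; this is the null under which the pipeline's Cliff's delta is
calibrated to vanish. (Note that equalising σ~W~ and σ~B~ at a nonzero
value does *not* produce a null: SSB neighbor groups mix bouton factors,
so their variance is σ~W~² + σ~B~² against σ~W~² within an MSB.)

`generate_neurite_tree()` grows trees that fan out from the soma inside a
cone (default half-angle 40°, 6 primary branches, 150 µm extent),
branching stochastically, then resamples them to 0.5 µm SWC. Fanned
geometry makes separate branches diverge with distance, reproducing the
qualitative proximity profile (high near the soma, falling off distally).

Neither generator attempts absolute realism: the synapse table does not
match empirical volumes or areas (only the relational structure), contacts
are placed on dendrites uniformly at random rather than by any spatial
rule, and the trees have no diameter taper, no tortuosity statistics from
real reconstructions, and no tissue boundaries. Tests passing on synthetic
data therefore validate the *estimators and pipelines* — that they recover
planted effects and stay calibrated under planted nulls — not any claim
about real tissue.

## Degenerate inputs and edge cases

Invalid count distributions (negative mass, sum ≠ 1 beyond 10⁻¹²) and a
requested active-zone count exceeding the CA1 population (distinct targets
impossible) raise configuration errors; matched plasticity assignment
before release probabilities exist raises an ordering error; unsorted
spike trains, empty analysis windows and single-neuron correlation
requests raise input errors. Empty variance groups warn and return empty
tibbles; trees with fewer nodes than requested bins warn and return fewer
bins. τ~fac~ = 0 is handled as instantaneous utilisation decay, and the
near-degenerate case τ~rec~ ≈ τ~syn~ in the closed-form propagator has an
explicit series guard.

## Known limitations

The model is purely feed-forward: no inhibition, no CA1 recurrence, no
conductance-based synapses, no dendritic compartments, and connectivity
carries no spatial geometry. The background-noise discretisation makes the
effective noise spectrum depend mildly on its update interval. The
analytic plasticity fixed point used in the tests neglects the finite PSC
decay (an O(τ~syn~/τ~rec~) ≈ 1% correction, which sets that test's
tolerance). Spike-train export is delimited text only. The proximity
analysis treats branches as polylines of nodes and ignores neurite
calibre.
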