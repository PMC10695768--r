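# msbnet

Multi-synaptic boutons (MSBs) are single presynaptic terminals in the
hippocampus that form active zones onto dendritic spines of *several
different* postsynaptic CA1 neurons, rather than the canonical one-bouton /
one-spine arrangement (SSBs). In the CA1 stratum oriens roughly 45% of
boutons are MSBs, and contacts made by one MSB are strikingly more similar
to each other than neighboring single-bouton synapses are. `msbnet`
provides the computational toolkit for studying what this wiring motif does
to population activity, and for the estimation statistics that establish
the within-bouton homogeneity in the first place:

- **Network model** — bouton-centric CA3/2 → CA1 connectivity with
  per-layer active-zone count distributions (stratum oriens ≈ 45% MSBs,
  stratum radiatum ≈ 25%), Gamma-distributed release probabilities
  (shape 2, scale 0.15, clipped at 1) and facilitating/depressing
  short-term plasticity identities, plus single-mechanism variants that
  isolate multiplicative connectivity, shared stochastic release, or shared
  plasticity.
- **Dynamics** — leaky integrate-and-fire CA1 neurons
  (τ<sub>m</sub> dV/dt = −V + R(I<sub>b</sub> + I<sub>syn</sub>)) driven by
  10 Hz Poisson sources through per-active-zone Bernoulli release and the
  Tsodyks–Markram three-state resource model
  (dx/dt = z/τ<sub>rec</sub> − u·x·δ(t−t<sub>sp</sub>), …,
  du/dt = −u/τ<sub>fac</sub> + U(1−u)δ(t−t<sub>sp</sub>)), integrated with
  exact exponential propagators in compiled code.
- **Correlation analysis** — the synchrony readout μ<sub>cc</sub>: the mean
  Pearson correlation of 20 ms binned spike trains over all CA1 pairs,
  orchestrated across the full grid of connectivity conditions with
  per-run reseeding.
- **Morphometrics** — within-MSB vs neighboring-SSB variance comparison
  with Cliff's delta, two-sided permutation tests (5000 reshuffles), BCa
  bootstrap intervals (5000 resamples), Ryan–Holm step-down adjusted
  confidence levels, and a dendrite self-proximity analysis on SWC
  morphologies (0.5 µm resampling, 5 µm threshold, 10 equal-count
  soma-distance bins).
- **Synthetic data** — generators for synapse-morphology tables (shared
  bouton-level lognormal factor, configurable within/between variance) and
  fanned dendritic trees, so every analysis is testable against known
  ground truth.

## Worked example

Does MSB connectivity synchronise CA1? A reduced-scale run (11 s simulated,
last 10 s analysed, 5 runs per condition):

```r
library(msbnet)

spec <- network_spec(sim_duration = 11, analysis_window = 10)
ssb <- run_condition(spec, condition = "ssb_all", n_runs = 5, master_seed = 1)
msb <- run_condition(spec, condition = "msb_all", n_runs = 5, master_seed = 2)
glance(dplyr::bind_rows(ssb, msb))
#> # A tibble: 2 × 7
#>   condition    n_runs mean_mu_cc sd_mu_cc     q25  median     q75
#>   <chr>         <int>      <dbl>    <dbl>   <dbl>   <dbl>   <dbl>
#> 1 full_msb_all      5    0.0139  0.000827 0.0134  0.0136  0.0145
#> 2 full_ssb_all      5    0.00491 0.000129 0.00483 0.00486 0.00500
```

Mean pairwise correlation roughly triples when both input layers contain
MSBs: one presynaptic spike copied (with shared release probability and
shared plasticity state) to several CA1 neurons is a common-input source
that single-synaptic wiring lacks. `run_experiment_suite()` runs the full
12-condition grid (four connectivity conditions, three single-mechanism
SSB/MSB pairs, and the release-probability-matched plasticity variant);
`autoplot()` shows the μ<sub>cc</sub> distributions.

The morphometric side, on a synthetic table with a planted bouton-level
factor (within-bouton log-SD 0.3, between-bouton 0.6):

```r
set.seed(7)
tab <- generate_synapse_table(synapse_gen_params(n_boutons = 200))
compare_bouton_variance(tab, "spine_volume")
#> Within-MSB vs neighboring-SSB variance of spine_volume
#>   96 MSB groups, 36 SSB groups
#>   mean difference (MSB - SSB): -0.001517  [-0.003218, -0.0007322] (95% BCa)
#>   Cliff's delta: -0.557   permutation p: 0.0003999
```

Spine volumes within one MSB vary far less than across neighboring SSBs
(negative Cliff's delta; the BCa interval for the mean variance difference
excludes 0), exactly the structure the generator planted. `tidy()` and
`autoplot()` give a one-row summary and a Gardner–Altman-style plot.

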