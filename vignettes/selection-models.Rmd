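---
title: "Selection models for host-associated microbiome evolution"
author: "holosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection models for host-associated microbiome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosim)
```

## The model

`holosim` simulates a constant-sized population of `N` asexual hosts across
discrete, non-overlapping Wright–Fisher generations. Every host carries a
microbiome: an integer count vector over `M` microbial OTUs whose total is
fixed at the capacity `C` ("slots" occupied by individual microbes). Nothing
else about a host is modeled except, under host-mediated microbial
selection, one heritable trait-score vector.

### Phenomes and the fitness map

Each OTU is assigned, once at the start of a run, a *phenome*: `m` distinct
traits sampled uniformly without replacement from a pool of `n` traits.
Phenomes are immutable — there is no mutation, recombination, or horizontal
transfer, so all evolutionary change is change in abundances.

Each trait carries two scores, each in {−1, 0, +1}: a *host-effect* score
(how the trait affects the fitness of the host in which the microbe lives)
and a *microbe-effect* score (how it affects the microbe's own chance of
being acquired). For any agent with mean trait score
$\beta = \tfrac{1}{m}\sum_j v_j \in [-1, 1]$, absolute fitness is

$$ f = s^{\beta}, \qquad w = f/s, $$

with `s ≥ 1` a selection coefficient (`s = 1` switches that selection off
and collapses the model to the neutral case, where every `f = w = 1`).
Thus `f ∈ [1/s, s]` and `w ∈ [1/s², 1]`, and over one host generation the
fittest agent is expected to out-reproduce the least fit by a factor `s²`.
The map is the one-generation integral of Lotka–Volterra exponential growth
without species interactions: growing at rate `α = β·a` for one host
generation `T`, with `a = ln(s)/T` (`lv_growth_rate()`), multiplies
abundance by exactly `s^β`.

### Acquisition and reproduction

Offspring build their microbiomes from a *source community* `S`
(`source_community()`): a convex mixture of `x`% the assigned parent's
relative abundances and `(100 − x)`% the environment (*mixed acquisition*,
MA_x). The environment itself (`assemble_environment()`) is `y`% the pooled
microbiomes of *all* parents and `(100 − y)`% a fixed, unchanging uniform
reservoir (*mixed environment*, ME_y). The limits recover pure parental or
environmental acquisition (`x = 100` / `x = 0`) and a purely host-derived or
fixed environment (`y = 100` / `y = 0`).

The `C` slots are filled by a single multinomial draw with probabilities

$$ p_i = \frac{f_i a_i}{\sum_k f_k a_k}, $$

abundance in the source reweighted by microbial fitness *in the acquiring
host's context*: under TMS, `f_i` comes from the universal microbe-effect
vector; under HMS, from the offspring's inherited lineage vector; with
microbial selection off, all `f_i = 1` and acquisition is the neutral
multinomial resample. OTUs absent from the source can never be acquired, so
support only shrinks (the fixed reservoir is the sole refuge).

Host reproduction is fitness-weighted Wright–Fisher: host trait score is the
abundance-weighted mean of its OTUs' host scores,
$\beta_{host} = \sum_i a_i \beta_i$, host fitness `f = s_h^β`, and each of
the `N` offspring draws its parent with probability `q_i = f_i / Σ f_k`.
The update is strictly two-phase: all parental fitnesses and the pooled
environment are computed from the parental generation's final microbiomes
before any offspring exists, so within-generation order cannot leak.

### The three selection regimes

* **HS** (`s_h > 1`): microbial traits alter host reproductive success.
* **TMS** (`microbial_mode = "tms"`, `s_m > 1`): one universal microbe-effect
  vector governs acquisition in every host.
* **HMS** (`microbial_mode = "hms"`, `s_m > 1`): each of the `N` founding
  lineages draws its own microbe-effect vector, inherited verbatim by all
  descendants; no new vectors ever arise, so the set of influence vectors
  present at any time is a subset of those created at seeding.

The *consistency* between host-level and microbe-level selection is the
cosine between the host-effect vector `h` and the microbe-effect vector `m`
active in a host,

$$ \cos\theta = \frac{\sum_k h_k m_k}{\sqrt{\sum_k h_k^2 \sum_k m_k^2}}, $$

averaged over hosts at the population level. A zero vector (one regime
exerting no influence) gives 0 by convention.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `N` | host population size | 500 | constant; large preset 5000 |
| `C` | microbiome capacity (slots/host) | 10^4 | large preset 10^9; same code path |
| `M` | number of OTUs | 150 | about the genus richness of a human body site |
| `n_traits` | trait-pool size | 10 | 25 in the large preset (KEGG-module scale) |
| `m` | traits per phenome | 5 | genome-size scaling: `round(3/14 × 25) = 5`, see `default_traits_per_phenome()` |
| `ma_percent` | parental % of acquisition (MA_x) | 50 | 0 = EA, 100 = PA |
| `me_percent` | parental % of environment (ME_y) | 50 | 0 = FE, 100 = PE |
| `s_h`, `s_m` | selection coefficients (≥ 1) | 1 | studied over {1, 10, 100, 1000} |
| `generations` | host generations | 10^4 | large preset 2×10^5 |
| `effect_probs` | P(−1, 0, +1) per trait score | uniform | see below |

Scale presets (`scale_presets()`) are data, not code: `small`
(N = 500, C = 10^4, M = 150, n = 10, G = 10^4, 50 replicates), `large`
(N = 5000, C = 10^9, n = 25, G = 2×10^5, 5 replicates), and `ci`
(N = 100, C = 2000, M = 40, G = 500, 5 replicates), a desk-scale bundle
that exercises the full sweep machinery in minutes.

## Design choices where the design was open

* **Trait sampling without replacement.** A phenome is a gene-content
  complement; a duplicated ±1 score summed twice has no biological reading,
  so phenomes are sets of distinct traits.
* **Effect-score distribution.** Scores are i.i.d. uniform over {−1, 0, +1}
  per trait per vector (and per lineage under HMS) — the maximum-entropy
  choice on the stated support — with the triple configurable
  (`effect_probs`). The universal host-effect and microbe-effect vectors are
  drawn *independently*, so the realized HS–TMS consistency varies across
  runs; that realized correlation is itself a studied quantity
  (`consistency_experiment()`).
* **Host score is abundance-weighted.** The host's trait score averages
  per-OTU scores weighted by relative abundance, which keeps
  `β_host ∈ [−1, 1]` and lets the same `f = s^β` map apply verbatim to hosts.
* **Mixing before sampling.** MA mixing builds the source community on
  abundances first, then draws once; the alternative of two separate draws
  (`x%` of slots from the parent, the rest from the environment) is available
  as `acquisition = "split"`. The two have identical marginal expectations.
* **The environmental pool is bookkeeping.** All `N` parents contribute to
  the pooled environment with equal weight, regardless of realized
  reproductive success, and no selection is applied at pooling: all
  selection acts at acquisition, in the acquiring host's context. Under HMS
  the acquiring offspring's (inherited) vector mediates microbial fitness
  even for environmentally acquired microbes.
* **Classification is universal.** Beneficial/commensal/pathogenic labels
  come from the sign of the summed *host*-effect scores, which are universal
  in every mode — under HMS only microbe effects are host-specific.
* **Log fold changes in base 10**, Shannon in natural log (both
  configurable); β diversity is the mean of all pairwise Bray–Curtis
  distances (subsampled to 10^5 random pairs above 1000 hosts, flagged in
  the output attribute).

## Randomness and reproducibility

Every run is reproducible from `(config, seed)`. Sweep drivers derive one
stream per (grid cell, replicate) with the documented splitting rule
`derive_seed(root, index) = (root·48271 + index·100003) mod (2³¹−1)`, where
the index encodes only the acquisition percentages and replicate number —
*not* the selection parameters — so panels that differ only in selection
strength run on common random numbers and paired comparisons are sharp.
Counts are exact integers (capacity is conserved identically, asserted in
tests); relative abundances are computed on demand in floating point, and
multinomial weights are normalized internally by the sampler.

## What the toy worlds emulate — and what they do not

The frozen toy presets (`make_toy_world()`: `two-otu`, `neutral`,
`antagonist`) are fully explicit two-host, two-OTU worlds whose one-step
expectations have closed forms (`expectation_oracle()`): acquisition
probabilities `p`, reproduction probabilities `q`, and expected offspring
counts `C·p`. Tests compare 10^5 Monte Carlo engine draws against these
oracles within four standard errors. The synthetic worlds emulate the
*mechanics* of the model, not any empirical microbiome: passing tests
demonstrate that the sampling machinery is correct and that the qualitative
selection effects appear at desk scale, not that real communities follow
this model.

## Desk-scale behavior and known limitations

The headline experiments in the test suite run at
N = 100, C = 2000, M = 150, n = 10, m = 5, G = 500 with 20–30 paired
replicates — sizes chosen so the full suite completes on one CPU in minutes
while keeping the community richness of the larger settings. Two desk-scale
effects are worth knowing about:

* **Drift is strong.** With few hosts, one HMS lineage fixes within a few
  hundred generations. Before fixation the *population mean* microbe
  relative fitness is inflated by lucky lineages (those whose influence
  vectors admit high-`w` communities); after fixation it settles at the
  surviving lineage's equilibrium. With few OTUs this can make the mean
  microbe fitness trajectory non-monotone even though acquisition is
  selective throughout; at M = 150 the concentration gain (roughly a factor
  `M` between a uniform and a concentrated community) dominates and the
  final-vs-initial increase is robust. This is why the directional fitness
  experiments keep `M = 150` while scaling everything else down.
* **Moderate selection for persistence questions.** At C = 2000 slots,
  `s = 100` acts at near-fixation strength; the composition experiment
  therefore uses the moderate `s_h = s_m = 10` cell of the studied grid,
  where the decline of commensals and pathogens with parental contribution
  and their persistence (fed by the fixed reservoir) are both visible.

Model-level exclusions (by construction, not oversight): no mutation, no
recombination or horizontal gene transfer, no epistasis, no host population
structure, no microbe–microbe interactions, and no environmental microbial
fitness or dispersal — the environment is a passive mixture. Hosts have no
genetics beyond the heritable HMS vector, no mortality separate from
reproduction, and generations do not overlap. Statistical testing beyond a
plain Pearson correlation is deliberately left to external tools; all run
and sweep tables are exported as plain TSV for that purpose.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(N = 100, C = 2000, M = 150, n_traits = 10, m = 5,
                  ma_percent = 50, me_percent = 50,
                  s_h = 100, s_m = 100, microbial_mode = "hms",
                  generations = 500)
run <- run_simulation(cfg, seed = 1, record_every = 100)
run$summary

spec <- sweep_spec(ma_percent = seq(0, 100, 25), me_percent = seq(0, 100, 25),
                   s_h = 1, s_m = c(1, 100), microbial_mode = "tms",
                   replicates = 5, scale = "ci", seed = 1)
sw <- run_sweep(spec)
heatmap_matrix(sw, "alpha", s_m = 100)
```
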