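---
title: "The informed-dispersal metapopulation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The informed-dispersal metapopulation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersim)
```

## The question the simulator addresses

Organisms deciding whether to leave their natal patch can rely on *direct*
information — cues they sample themselves, such as local crowding — or on
*indirect* social information, cues about the wider landscape they cannot
sample, such as the arrival of immigrants (an immigrant proves that other
populations exist and, when dispersal is density-dependent, carries a hint
about how full they are). `dispersim` implements an individual-based
metapopulation model in which both kinds of information use are heritable
and free to evolve, so one can ask under what conditions each evolves,
whether they can coexist, and what they do to metapopulation persistence.

## The model

### Demography

The life cycle is female-based, haploid and clonal, with two reproductive
age classes on a yearly time step. Individuals are juveniles from birth to
age 1, subadults from 1 to 2, and adults after 2. Survival is an
independent Bernoulli draw per individual at age-specific rates
$s_0, s_1, s_2$; survivors advance one class. Every subadult and adult then
breeds, with Poisson-distributed offspring counts (means $f_1$, $f_2$).
Total patch size at the reproduction census is hard-capped at the carrying
capacity $K$: breeders are processed in a uniformly random order and births
beyond the cap are discarded, so no parent is systematically favoured.
There is no other density dependence. The default rates
($s_0 = 0.2$, $s_1 = 0.35$, $s_2 = 0.5$, $f_1 = f_2 = 7$, $K = 100$) are a
"fast" life history, roughly a small lizard or passerine; one generation is
about two time steps, which is what `steps_to_generations()` assumes when
converting. All of these are free parameters of `life_history()` and
`sim_config()`.

Each offspring inherits its parent's dispersal genotype — the coefficients
$D$ and $I$ below, plus a logit-scale uninformed trait $U$ in the
evolvable-$U$ variant. Each locus independently mutates with probability
0.02 per offspring, adding a Gaussian step with standard deviation 0.02.
The coefficients are unbounded reals: drift may take them negative, which
is exactly what the sign-based evolution criterion exploits.

### Dispersal decisions

Only juveniles disperse. Each time step, after reproduction, every juvenile
in the metapopulation is visited once in a global uniformly random order
(re-randomized each step). The visit order matters because information is
*live*: a juvenile deciding early sees its patch before any immigrant has
arrived this step, while later deciders see updated densities and immigrant
counts. Each decision is two-staged:

1. **Uninformed baseline.** With fixed probability $d_U$ (default 0.1) the
   juvenile disperses regardless of any cue. This both alleviates kin
   competition and seeds the immigrant cue — without it, immigrant-dependent
   dispersal alone can never bootstrap (the configuration validator warns
   about this combination).
2. **Informed dispersal.** Otherwise the juvenile disperses with
   probability $\min(1, d_D + d_I)$, where each channel is the logistic
   transform $d(x) = 1/(1+e^{-x})$ of a linear behaviour function of its
   cue:
   $$B_D = D\,\frac{n_i}{K_i} - 2, \qquad B_I = I\,M_i - 2,$$
   with $n_i$ the current resident count of the natal patch and $M_i$ the
   number of immigrants that have already arrived there during the current
   dispersal phase. The immigrant channel is only expressed when
   $M_i > 0$. A realized informed event is attributed to one strategy by a
   draw proportional to $d_D$ and $d_I$; these attributions, divided by
   metapopulation size, are the *realized* per-strategy dispersal rates.

The fixed intercept $-2$ sets each channel's floor at
$d(-2) \approx 11.9\%$, so selection acts on the slope of the reaction norm
rather than waiting for dispersal to arise from zero. Model variants
(`U_only`, `D_only`, `I_only`, `D_and_I`) control which channels are
expressed. A disperser is assigned a destination uniformly among the other
patches (the landscape has no geometry: all patches are equally connected),
is immediately counted in the destination's $M_i$ and density, and pays the
dispersal cost — if configured — as a multiplicative reduction of its
subsequent juvenile survival, $s_0(1-c)$. Charging the cost at the next
survival step keeps the dispersal phase conservative (it never changes the
number of individuals) while remaining probabilistically equivalent to
dying in transit; the arrival is counted as an immigrant either way, which
is the ordering the model intends.

### Time step, initialization, termination

A step applies, in order: environmental catastrophes (if configured),
survival, the benefit census (below), reproduction with mutation, and the
dispersal phase. Runs start from 100 identical subadults (capped at $K$) in
a single patch, with $D = I = 0$ — i.e. both informed channels exactly at
the 12% floor — and every other patch empty, so the first phase of every
run is a colonization sweep. A run ends at `n_steps` or when the
metapopulation is empty; the step at which it emptied is the persistence
time.

Environmental stochasticity is modelled as whole-patch catastrophes: each
patch is independently hit with probability `env_stoch_prob` per step, and
a hit kills each resident with probability `env_stoch_severity` (default
1, i.e. the patch is wiped). The mechanics of a "hit" are a design choice
of this package, as is applying catastrophes before survival; both are
configurable only through these two parameters.

### Measures

* **Evolution criterion.** A strategy has evolved in a replicate if its
  population-mean coefficient at the final step is strictly positive;
  under drift alone positive and negative final means are equally likely,
  so a batch of replicates is tested with an exact two-sided binomial
  sign test against 0.5 (`sign_test()`). Extinct replicates carry no
  final coefficient and are excluded from the test (and classified
  `none`). The `U_only` variant doubles as the matched neutral control:
  its $D$ and $I$ loci mutate but are never expressed, so their final
  signs are pure drift.
* **Benefit of dispersal.** For each disperser, the ratio of origin to
  destination patch density measured right before the next reproduction
  (a ratio above 1 means the move found a less crowded patch). The
  trajectory row for step $t$ reports the mean ratio for step $t-1$'s
  dispersers; dispersers whose destination is empty at the census are
  excluded and counted.
* **Reaction norms.** `reaction_norm()` evaluates the logistic behaviour
  function at the mean evolved coefficient over a cue grid, with a 95%
  band from the among-replicate spread of the coefficient
  (mean $\pm 1.96\,$SD, a normal approximation).
* **Extinction metrics.** Per-batch extinction fraction and the
  persistence-time distribution of the extinct replicates.

## Numerical and implementation choices

* **Two engines, one semantics.** The exported step operations
  (`survive()`, `reproduce()`, `mutate()`, `dispersal_phase()`,
  `sim_step()`) are pure R and define the model; `run()`'s compiled core
  re-implements the full loop in C++ for speed. Both consume R's RNG
  stream draw for draw — permutations are generated as
  `order(runif(n))`, destinations as `floor(runif(1) * (P - 1))` — so for
  a given seed the two paths produce *identical* trajectories, which the
  test suite asserts across variants. Determinism is therefore exact:
  one `(config, seed)` pair, one trajectory.
* **Mutation applies to $D$ and $I$ in every variant** (and to $U$ only
  when evolvable). Inactive coefficients drift neutrally; this costs a
  few random draws but provides the neutral control for free and keeps
  the genotype's meaning identical across variants.
* **Per-locus mutation.** The mutation probability is interpreted per
  locus, not per genotype, so the two coefficients evolve independently.
* **The cap discards rather than rations.** When a breeder's Poisson draw
  overshoots the remaining room, the excess births are discarded; the
  random breeder order makes the truncation unbiased.
* **Live counters in the dispersal phase.** A decider's density cue
  includes immigrants that already arrived and excludes emigrants that
  already left, in both its natal and (for arrivals) destination patch;
  the within-step immigrant counter is reset at the start of every phase.
* **Overflow safety.** The logistic is evaluated through `plogis()`;
  behaviour values of any magnitude yield probabilities in $[0, 1]$
  without `NaN`.
* **Degenerate inputs.** `n_steps = 0` produces the initial census only;
  a single-patch landscape cannot disperse (warning); empty patches pass
  through every operator unchanged.
* **Evolvable $U$** is initialised at `qlogis(d_U)` so that variant
  starts at the same realized uninformed rate as the fixed one;
  `d_U` of exactly 0 or 1 is rejected there because the logit is
  undefined.

## Scale of the shipped experiments

The model's full-scale regime uses 100 replicates of
$1.5\times10^6$ steps (the default `n_steps` and `monte_carlo()`
replicate count); the package's own tests and the acceptance script
run the same study design at a desk scale chosen once: 10 patches,
$K = 100$, $10^5$ steps, 20 replicates per variant batch. At this scale
density- and immigrant-only batches already show a strong positive bias of
the evolved coefficients, and the joint model shows coexistence, while the
neutral control stays at drift. The small-$K$ extinction comparison uses
$K = 12$, 10 patches, $2\times10^4$ steps. That capacity was fixed once as
the demographic-stress window for the fast life history: the window in
which whole-metapopulation extinction is common but not immediate — small
enough for demographic stochasticity to empty patches, large enough for
recolonization to matter — which is the regime where information use is
expected to affect persistence. The shipped stress batches run in this
partial-extinction regime.

## What the generator does and does not emulate

Synthetic data from this model captures demographic stochasticity at small
$K$, kin structure through clonal patches, the information asymmetry
between early and late deciders within a step, and catastrophe-driven
spatial heterogeneity. It does **not** emulate: spatial geometry or
distance-dependent dispersal, habitat-quality differences between patches,
diploid genetics or sex structure, immigrant-borne information beyond the
bare arrival (real immigrants may reveal their origin's density), or costs
that differ between information sources (the configuration keeps a single
dispersal cost). Conclusions from passing tests therefore concern this
idealised landscape; they say nothing about, e.g., whether information use
survives realistic patch-quality variation.

## Known limitations and quirks

* The evolution criterion is the strict sign of the final population mean;
  the alternative drift-threshold criterion sometimes used for such models
  is out of scope.
* With 20 replicates the sign test needs at least 15 positives for
  $p < 0.05$; desk-scale batches of the joint model's *density* channel —
  the weakest published effect — are not expected to clear significance,
  and the tests only require it to stay at or above drift level.
* A published sign-test value for the joint model's density channel
  (65/100 positive, $P = 0.035$) is not reproducible by an exact two-sided
  binomial test, which gives $\approx 0.0035$ for 65/100; this package
  reports the exact binomial value.
* Trajectory records are thinned (default: every 100th step plus the
  final one); per-event logs are only collected on request and are meant
  for short runs.
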