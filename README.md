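# dispersim

An individual-based, discrete-time metapopulation simulator for studying
how **informed natal dispersal** evolves. Juveniles may emigrate at a fixed
uninformed baseline rate, or according to heritable reaction norms that
respond to

* **local density** (direct information: the cue itself determines fitness),
* the **number of immigrants** arriving in the natal patch during the same
  time step (indirect social information: evidence about the rest of the
  landscape that the individual never samples directly),

or both at once. The package is aimed at eco-evolutionary modellers who
want a fast, fully reproducible implementation of this model family,
together with the statistics used to decide whether each form of
information use evolves and what it buys the metapopulation.

## The model in brief

Two-age-class, female-based, haploid-clonal demography on `n_patches`
equally connected patches: Bernoulli survival (s₀, s₁, s₂), Poisson
fecundity (f₁, f₂) hard-capped at the carrying capacity K at reproduction,
per-locus Gaussian mutation (rate 0.02, SD 0.02) of the heritable
coefficients. Each juvenile decides in a globally randomized order:
first an uninformed Bernoulli(d_U) draw, then informed dispersal with
probability min(1, d_D + d_I), where

    B_D = D · n/K − 2      d_D = 1 / (1 + exp(−B_D))
    B_I = I · M  − 2       d_I = 1 / (1 + exp(−B_I))   (only when M > 0)

with `n` the live resident count and `M` the count of immigrants already
arrived this step. The −2 intercept puts each channel's floor at
plogis(−2) ≈ 12%. Evolution of a strategy in a replicate is judged by the
sign of the final population-mean coefficient; batches are tested with an
exact two-sided binomial sign test against the 50% expected under drift.

The step operations are exported as pure R functions (`survive()`,
`reproduce()`, `mutate()`, `dispersal_phase()`, `sim_step()`); `run()`
executes the same semantics in a compiled core that reproduces the R
reference **bit for bit** on a shared seed (asserted in the test suite).
See the vignette `vignettes/informed-dispersal-model.Rmd` for the full
model description and design notes.

## Worked example

```r
library(dispersim)

cfg <- sim_config(variant = "D_only", n_patches = 10, K = 100,
                  n_steps = 1e5)
r <- run(cfg, seed = 1)
r
#> <replicate_result> variant = D_only  seed = 1
#>   steps: 100000
#>   final means: D = 1.3032  I = -0.3459  U = -2.1972
#>   final-window realized rates: U 0.0762  D 0.2173  I 0.0000
```

The density coefficient evolved from 0 to D ≈ 1.3: juveniles in a
crowded patch (n ≈ K) now disperse with probability plogis(1.3 − 2) ≈ 33%
through the density channel alone, against the 12% floor they started at,
and the realized density-informed dispersal rate (events per capita per
step, ≈ 0.22) has overtaken the fixed 10% uninformed baseline (realized
≈ 0.08 of the whole metapopulation per step). The unexpressed immigrant
coefficient drifts (here to −0.35) — in a batch of replicates its final
sign is a fair coin, which is exactly the drift null the sign test uses:

```r
b <- monte_carlo(cfg, n_replicates = 20, base_seed = 101)
rpt <- batch_report(b)
rpt$density
#> $n_positive
#> [1] 19
#>
#> $n_tested
#> [1] 20
#>
#> $p_value
#> [1] 4.005432e-05
```

19 of 20 replicates ended with a positive density coefficient
(p ≈ 4e-5): density-informed dispersal reliably evolves even in this
stable, homogeneous landscape. `reaction_norm()` turns evolved
coefficients into dispersal-probability curves, `dispersal_benefit()`
measures how much less crowded the patches found by dispersers are, and
`extinction_metrics()` summarises persistence under stress (small K or
environmental catastrophes).

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/dispersim`:

```sh
Rscript inst/scripts/dispersim run --variant D_only --n-steps 100000 \
    --seed 1 --out d.tsv
Rscript inst/scripts/dispersim batch --variant D_and_I --replicates 20 \
    --base-seed 1 --summary-out b.tsv --report-out b.json
Rscript inst/scripts/dispersim analyze --summary b.tsv --out-prefix an
```

All outputs are plain TSV/JSON with the fully resolved configuration and
seed embedded in `#` header lines, so every file is self-describing and
byte-reproducible.

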