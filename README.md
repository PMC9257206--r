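# habRI

Quantifying sequential reproductive isolation (RI) barriers between
co-flowering plant species from raw field observations.

## The problem

Closely related, sympatric plant species stay distinct because a series of
reproductive barriers acts along the life cycle: flowering at different
times, pollinators that forage faithfully on one species, pollen tubes that
fail in a foreign style or ovary, fruits that abort, embryos that never
develop. Speciation studies need each barrier's strength, and — because a
barrier can only block what earlier barriers let through — each barrier's
*absolute contribution* to total isolation. habRI computes all of this for
a species pair from three kinds of field data:

- **flowering records** (one row per individual: first and last flowering
  day) → phenological isolation;
- **pollinator foraging bouts** in two-species choice arrays (ordered
  visit sequences) → ethological isolation, per-pollinator constancy, and
  a likelihood-ratio G-test of intra- vs interspecific transitions;
- **hand-pollination experiments** (pollen-tube counts per pistil, fruit
  set, embryo scoring) → style, ovary, fruit and seed barrier strengths.

## The indices

For one barrier with conspecific success *C* and heterospecific success
*H*:

    RI = 1 − 2·H/(H + C)

so RI = 1 is complete isolation, 0 none, negative values a heterospecific
advantage. Phenological isolation uses the shared/unshared flowering
proportions *S*, *U* of the focal species: RI_pheno = 1 − S/(S + U).
Pollinator constancy per foraging bout is CI = (c − e)/(c + e − 2ce) with
e = p² + (1 − p)². Barriers combine sequentially,

    RI[1,i] = RI[1,i−1] + RI_i·(1 − RI[1,i−1]),     AC_i = RI[1,i] − RI[1,i−1]

so the absolute contributions AC_i telescope exactly to the total. A
flowering-weighted total, 1 − 2(S·Hs + U·Hu)/[(S·Hs + U·Hu) + (S·Cs + U·Cu)],
is reported alongside. Directional asymmetry is |RI_ab − RI_ba| per
barrier.

## Worked example

The package ships hawkmoth transition counts from choice arrays of three
*Habenaria* orchids (*H. limprichtii* "lim", *H. davidii* "dav",
*H. delavayi* "del"):

```r
library(habRI)
tab <- habenaria_transitions("lim_dav")
tab
#> Floral transition counts (from row to column):
#>      to
#> from  lim dav
#>   lim  16   3
#>   dav   1  14
#> intraspecific: 30  interspecific: 4

ethological_ri(tab, focal = "lim")   # 0.8823529
ethological_ri(tab, focal = "dav")   # 0.6470588
g_test_transitions(30, 4)
#> G = 22.504, df = 1, p-value = 2.097e-06
```

Moths moved overwhelmingly between flowers of the same species: only 4 of
34 transitions crossed species, giving strong ethological isolation for
both species (0.882 and 0.647) and decisively rejecting random foraging.

A full analysis runs from the five observation tables; here on a
simulated dataset whose generator mimics the field design:

```r
cfg <- sim_config(seed = 42)
dat <- simulate_dataset(cfg)
fit <- ri_isolation(
  phenology = dat$phenology, bouts = dat$bouts,
  pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds,
  pair = c("A", "B")
)
fit$cascades[["A x B"]]
#> Sequential reproductive isolation cascade: A (female) x B (male)
#>      barrier     ri estimable cumulative contribution
#>    phenology  0.178      TRUE      0.178        0.178
#>  ethological  0.838      TRUE      0.867        0.689
#>        style  0.018      TRUE      0.869        0.002
#>        ovary -0.032      TRUE      0.865       -0.004
#>        fruit -0.009      TRUE      0.864       -0.001
#>         seed  0.070      TRUE      0.873        0.010
#> Total RI (sequential): 0.873
#> Total RI (phenology-weighted): 0.876
```

Reading the table: the two species' flowering windows overlap widely
(phenology RI 0.178), pollinator fidelity is the dominant barrier
(contribution 0.689 of the 0.873 total), and the post-pollination stages
add almost nothing — the generator's defaults emulate exactly that common
empirical pattern. `summary(fit)` adds the per-barrier asymmetry table,
`coef(fit)` the barrier-by-direction RI matrix, `plot(fit)` the
contribution/cumulative figure, and `ri_bootstrap()` percentile intervals.

A thin command-line wrapper (`inst/cli/ri_pipeline.R`) exposes
`simulate`, `barriers`, `total` and `fixtures` subcommands over the same
functions.

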