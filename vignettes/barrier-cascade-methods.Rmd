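---
title: "Quantifying sequential reproductive isolation barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sequential reproductive isolation barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habRI)
```

## The model

habRI decomposes reproductive isolation between two co-flowering plant
species into a fixed life-cycle sequence of barriers: flowering
phenology, pollinator foraging behaviour (ethological isolation), pollen
tube entry into the style, pollen tube entry into the ovary, fruit set,
and seed (embryo) development. Every barrier is scored on the same
scale,

$$RI = 1 - 2\,\frac{H}{H + C},$$

where $C$ is conspecific and $H$ heterospecific reproductive success at
that stage. $RI$ is 1 when heterospecific success is nil, 0 when both
are equal, and negative when heterospecific crosses do *better* — a real
possibility that the package propagates unchanged rather than clipping.
The index is invariant to a common scale factor, so counts and
proportions are interchangeable within one barrier; the ingestion layer,
not the index, is responsible for not mixing units.

Phenological isolation uses the same logic on flowering time: for a
focal species, $S$ is the fraction of its flowering days shared with the
partner and $U = 1 - S$ the unshared fraction, giving
$RI_{pheno} = 1 - S/(S+U) = U$. The measure is directional: a species
flowering briefly inside its partner's long season is not isolated, but
the partner is.

### Sequential combination

A barrier can only block gene flow that earlier-acting barriers let
through. The cumulative isolation after barrier $i$ follows

$$RI_{1,i} = RI_{1,i-1} + RI_i\,(1 - RI_{1,i-1}), \qquad RI_{1,0} = 0,$$

equivalently $1 - RI_{1,i} = \prod_{j \le i} (1 - RI_j)$: the fraction
of heterospecific gene flow surviving the cascade is the product of the
per-barrier survival fractions. Each barrier's absolute contribution is
the telescoping difference $AC_i = RI_{1,i} - RI_{1,i-1}$, so
$\sum_i AC_i$ equals the total exactly, and a single complete barrier
($RI_i = 1$) pins the cumulative value at exactly 1 (the implementation
returns the exact value, not a floating-point neighbour). One
consequence worth stating plainly: the product identity bounds the
cumulative value above by 1 but *not* below by $-1$ — several
successive barriers with heterospecific advantage can drive it below
$-1$. The tests assert the identities that actually hold (always
$\le 1$; within $[0,1]$ for non-negative ladders) rather than a bound
the recurrence does not have.

The combination rule itself is a design choice: the contribution
definition $AC_i = RI_{1,i} - RI_{1,i-1}$ does not by itself say how
$RI_{1,i}$ is built. We use the discounting recurrence above because it
is the standard sequential-acting formalisation, reproduces complete
totals exactly whenever any barrier is complete, and lands within 0.01
of published totals built from comparable ladders.

### Weighted total isolation

A second total weights end-to-end success by the shared/unshared
flowering proportions:

$$RI_{total} = 1 - 2\,\frac{S H_s + U H_u}{(S H_s + U H_u) + (S C_s + U C_u)}.$$

$H_s, C_s$ are the end-to-end heterospecific/conspecific success during
the shared flowering period — products of per-stage success proportions
over the post-phenology barriers. A barrier's RI value $r$ determines
its normalised success pair ($h = (1-r)/2$, $c = (1+r)/2$), which is
what the products use. By default $H_u = 0$ (no heterospecific pollen
arrives outside the shared period) and $C_u = C_s$ (conspecific success
is unaffected by the partner's absence). With $U = 0$ the formula
collapses exactly to the single-stage index, a degeneracy the test
suite checks. Both totals — recurrence and weighted — are reported side
by side; they typically differ in the second or third decimal and
neither is declared canonical, since field studies have used both
conventions.

## Per-module choices

**Phenology.** Day resolution is integer days: field phenology is
typically censused every few days, so sub-day precision would be
spurious. ISO dates are converted to day-of-year. A species' window is
the *union* over individuals of closed $[\mathrm{first},\mathrm{last}]$
intervals — population-level phenology, not per-individual averaging —
and both endpoints count as flowering days. Sites are pooled by
default, with a per-site mode for within-site isolation.

**Foraging.** Transitions are consecutive visit pairs within a bout;
bouts never chain (a single-visit bout contributes no transitions). For
ethological RI of a focal species, $C$ is focal→focal transitions and
$H$ transitions *into* the focal species from the other — the moves
that put heterospecific pollen on focal stigmas; this orientation is
the one that reproduces all published per-direction values we checked
against. The constancy index
$CI = (c-e)/(c+e-2ce)$, $e = p^2 + (1-p)^2$, is computed per bout with
$c$ the proportion of conspecific moves and $p$ the proportion of
visits to the first array species; a bout confined to one species has
$c = 1, e = 1$ and takes the limit value 1. Pollinator summaries report
the mean and sample SD over estimable bouts, with a lone bout reported
as SD 0 and flagged by `n_bouts = 1` (the convention of published
constancy tables). The G-test is the likelihood-ratio goodness-of-fit
statistic $G = 2\sum O_i \ln(O_i/E_i)$ with equal expected counts and
one degree of freedom, no continuity correction — the equal-split null
is a modelling choice about foraging, not a claim about plant
availability, and zero cells contribute nothing to the sum.

**Crosses.** Style and ovary success are the *mean per-pistil
proportions* (tubes in style / tubes on stigma; tubes in ovary / tubes
in style), which are robust to unequal pollinia loads across pistils; a
raw-count mode (`mode = "count"`) is provided for sensitivity analysis
because protocols are sometimes phrased in terms of summed tube counts,
and the data do not always disambiguate the two. Pistils with no tube
in the style are excluded from the conditional ovary proportion. Fruit
success is the fruit-set proportion; only dense, turgid capsules count
(`fruit_call()`), though empty capsules are retained for embryo
scoring. Seed success is the pooled large-embryo rate over fruits,
which equals the seeds-scored-weighted mean of per-fruit rates.
Self-pollinations are carried through validation but excluded from
interspecific RI: they measure compatibility, not isolation.
Routine treatment comparisons (Kruskal–Wallis with Dunn post hoc,
binomial GLMs) belong to the standard statistics stack and are not
re-implemented here.

**Cascade assembly.** Barriers that cannot be estimated (no shared
pollinators, a missing experimental arm) are flagged and *skipped*, not
zero-filled — zero-filling would silently reassign their contribution
to later barriers. Undefined indices ($C + H = 0$) raise a typed
condition (`ri_undefined_error`) naming the barrier and direction, so
report generation can mark them "not estimable" instead of receiving a
sentinel value.

**Bootstrap.** `ri_bootstrap()` resamples raw observations with
replacement independently within each arm (bouts; pistils, flowers,
fruits within treatment arm), recomputes the full cascade per
replicate, and returns percentile intervals. The seed is mandatory and
the result is bit-for-bit reproducible under it. Arms with fewer than
five observations flag the interval as unstable. The default of 2000
replicates is the usual percentile-bootstrap recommendation.

## The synthetic-data generators

The generators produce datasets with the statistical structure the
analysis assumes, so the full pipeline is testable end to end:

- **Phenology**: per-individual start day ~ rounded Normal, duration
  $\max(1, \text{rounded Normal})$. Defaults (about 30 individuals per
  species, month-long windows starting in early July a few days apart)
  mirror a sub-alpine orchid meadow study design.
- **Foraging**: a one-parameter Markov bout model. The first visit
  follows relative abundance; each later visit stays conspecific with
  probability $\kappa + (1-\kappa)\,a_{\text{current}}$. $\kappa$
  interpolates between abundance-random foraging ($\kappa = 0$,
  expected ethological RI 0) and perfect constancy ($\kappa = 1$, RI
  and every CI exactly 1) — the simplest model reproducing both limits.
  Bout lengths are $1 + \text{Geometric}$ with mean 3 visits, matching
  the roughly 3 visits per bout of the field arrays the package's
  fixture comes from.
- **Crosses**: stigma loads are truncated Poisson ($\ge 1$), style and
  ovary counts binomial thinnings (so the nesting invariant holds by
  construction), fruit set Bernoulli per flower, and each fruit's
  roughly 300 scored seeds one multinomial draw over the four embryo
  classes (large, small, aborted, empty).

Every generator is deterministic under the config seed, and the
generated CSV schemas round-trip through the package's readers.

What the generators do *not* emulate: spatial array geometry and
distance-dependent foraging, pollinator arrival rates, among-year
phenological variation, overdispersion beyond binomial/multinomial
sampling, and any correlation between stages within a pistil beyond the
binomial chain. Passing the parameter-recovery suite therefore shows
the estimators are correct for this generating process, not that field
data meet its assumptions.

## Problem sizes and numerical conventions

The test suite exercises the estimators at realistic desk scale: 500
replicate simulations for the null and recovery checks (arms of 12–40
pistils, 24–60 flowers, 6–20 fruits), 1000 random ladders for the
telescoping identity, and bootstrap runs of 100–200 replicates (the
package default stays at 2000). Ties and degenerate inputs follow the
conventions above: exact 1 for complete barriers, typed errors for
undefined indices, `NA` for non-estimable quantities.

## Known limitations

- The two totals (recurrence vs flowering-weighted) genuinely differ;
  published totals built with undocumented weighting can match neither
  to the third decimal. Tolerances, where we compare, reflect that.
- Constancy summaries for pollinators with mixed bouts depend on the
  individual bout sequences; aggregate transition tables do not
  determine them.
- The cascade is a two-species decomposition; no multi-species
  generalisation of the index is attempted.
- Late post-zygotic barriers (hybrid germination, sterility) are out of
  scope — the data types end at embryo scoring.
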