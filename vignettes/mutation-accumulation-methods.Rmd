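---
title: "Methods: estimating mutational parameters from nested MA fitness assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating mutational parameters from nested MA fitness assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## The experimental design this package models

A mutation-accumulation (MA) experiment propagates many replicate lineages
through repeated single-individual bottlenecks, so that selection is almost
powerless (only mutations with roughly $4 N_e s < 1$ accumulate freely) and
lineages diverge by the random input of new mutations. `mutacc` targets the
*second-order* variant of this design: a set of first-order MA lines, each
expanded into its own set of second-order MA sublines that accumulate
mutations for a further $t$ generations, assayed side by side with control
"pseudolines" — replicate cultures recovered from the cryopreserved
first-order ancestor, genetically homogeneous by construction. The nesting
is line / treatment (control vs MA) / subline / replicate worm, and every
observation is a worm's offspring count on each of a few reproduction days.

## Demographic relative fitness

Absolute fitness $W$ is lifetime reproductive output. Because genotypes can
differ in the *timing* as well as the amount of reproduction, the pipeline
uses the demographic relative fitness

$$w_i = \sum_x e^{-r_0 x}\, l_x m_x(i),$$

where $l_x m_x(i)$ is worm $i$'s realized survivorship $\times$ fecundity
product at age $x$ (its offspring count on that day) and $r_0$ solves

$$\sum_x e^{-r_0 x}\, \bar l_x \bar m_x = 1$$

on the mean schedule of the assay's control worms. The left side is
strictly decreasing in $r_0$, so the root is unique; `solve_r0()` brackets
it in $[-10, 10]\,\mathrm{day}^{-1}$ and refines by bisection plus a Newton
polish to an absolute residual below $10^{-10}$ (robustness was preferred
over speed; the function is smooth and monotone, so this is never the
bottleneck). One $r_0$ per assay, shared by control and MA worms; a
re-assay gets its own controls and hence its own $r_0$. A worm with no
offspring has $w = 0$ exactly — $r$ is never estimated per individual. The
control mean of $w$ is 1 by construction, which is what lets fitness be
compared across lines whose absolute output differs several-fold.

Two conventions were genuinely open and are flags:

- **Averaging the control schedule.** The mean $\bar l_x \bar m_x$ is taken
  over control *individuals* by default; `weight_by_line = TRUE` averages
  per-line mean schedules instead (the two differ only in unbalanced
  designs).
- **Assay ages.** Reproduction-day ages default to 4.75, 5.75, 6.75 days
  but are per-assay configurable (`assay_table(ages = ...)`), since
  lineages with altered generation times may be assayed on shifted days.

## Decay of the mean and mutational variance

With the control mean fixed at 1, the per-generation mutational decay of
mean fitness is $\Delta M_w = (\bar w_{MA} - 1)/t$, negative when fitness
declines; under a rate $U$ of mutations with mean effect $E[a]$,
$\Delta M_w = -U\,E[a]$.

The mutational input of genetic variance is estimated from the among-subline
variance components: $V_M = \max\{0, (V_{L,MA} - V_{L,0})/2t\}$. The floor
matters: sampling noise can put the MA component below the control
component, and a negative mutational variance carries no information.
Components are estimated by `fit_oneway_components()` either by the
closed-form one-way ANOVA (method of moments, with the standard unbalanced
coefficient $k_0$) or by REML; both truncate the among-group component at
zero, and they coincide on balanced data whenever the untruncated moment
estimate is non-negative. The moments estimator is the default inside the
bootstrap because it is closed-form and runs thousands of times per line;
REML sits behind a flag.

Variances are reported under two standardizations:

- **ancestral-mean scale** (raw $w$): the scale on which the Bateman–Mukai
  estimators are consistent;
- **own-group-mean scale** $w^* = w_i/\bar w_{\text{group}}$: the
  "opportunity for selection" scaling, $\mathrm{Var}(w^*) =
  \mathrm{Var}(w)/\bar w^2$, appropriate for comparing variances between
  groups whose means differ. $V_{M*}$ and the mutational heritability
  $h^2_M = V_{M*}/\bar V_{E*}$ (with $\bar V_{E*}$ the average of the
  control and MA within-subline components) use this scale.

## Bateman–Mukai bounds

Assuming equal mutational effects,

$$U_{MIN} = \frac{2\,\Delta M^2}{V_M}, \qquad
  E[a]_{MAX} = \frac{V_M}{2\,\Delta M}.$$

These satisfy $U_{MIN} \cdot E[a]_{MAX} = \Delta M$ and $U_{MIN} \cdot
E[a]_{MAX}^2 = V_M/2$ identically. Under a *distribution* of effects,
$U_{MIN}$ underestimates the rate and $|E[a]_{MAX}|$ overestimates the mean
effect (the classic biases, reproduced by the package's own simulations).
When $\Delta M \ge 0$ or $V_M = 0$ no meaningful estimate exists;
`bateman_mukai()` returns an explicitly flagged missing value, never a
numeric sentinel, and flags (but returns) the nonsensical case
$|E[a]_{MAX}| > 1$. Downstream summaries drop flagged-missing values.

A practical warning that shapes several design choices below: $U_{MIN}$ is
a ratio with a denominator that can be arbitrarily close to zero. Its
sampling distribution at realistic design sizes is extremely heavy-tailed —
the estimated $V_M$ has positive probability density at $0^+$, so the
*mean* of $U_{MIN}$ over replicated experiments does not even exist, while
its median is well behaved. Medians are therefore the meaningful summary of
Bateman–Mukai estimates across lines or simulated experiments, and the
package's group summaries report both.

## Bootstrap

`bootstrap_line()` resamples *sublines* with replacement (all replicates of
a drawn subline together), separately within the control and MA strata —
the subline is the independent unit, and resampling below it would fake
precision. Per resample, group means are recomputed from unweighted subline
means, components refitted per stratum, $\Delta M_w = (\bar w_{MA} - \bar
w_0)/(\bar w_0 t)$ and the floored $V_M$ recomputed. Point estimates are
means over resamples (1000 by default), intervals the middle 95%
percentiles, and $U_{MIN}$/$E[a]_{MAX}$ are computed *from the bootstrap
means* — the ratio of means, not the mean of per-resample ratios, for the
heavy-tail reason above. Resamples with zero among-subline variance in both
strata are retained ($\Delta M$ is still defined, $V_M = 0$); there is no
rejection sampling. A fixed seed makes the bootstrap bit-reproducible.

## Re-assays and group summaries

A line assayed twice (e.g. after an anomalous first assay) is kept as two
assay tables with distinct `assay_id`s; each assay gets its own $r_0$ and
its own per-line estimates, and `group_summary()` merges at the *estimate*
level — the line contributes the unweighted mean of its per-assay values,
with flagged-undefined values dropped — rather than pooling raw data, so
one large re-assay cannot silently dominate. Group means are unweighted
means over line values; "all" averages over all lines.

## The hierarchical model

`fit_hierarchical_model()` fits
$w \sim \mathrm{Gmax} + \mathrm{Gmax}{\times}\mathrm{Fitness}$ with random
effects for line (MA stratum only) and subline, the among-subline variance
estimated separately in each Fitness $\times$ Treatment stratum via
dummy-coded random-effect terms. Defining each line's control mean as 1 is
equivalent to omitting the Fitness main effect and constraining the
among-line variance of controls to zero, and the model is parameterized
exactly that way. Fixed effects are tested with Satterthwaite degrees of
freedom (`lmerTest`) — a deliberate, documented substitute for the
Kenward–Roger-style adjustments of other software, which this package does
not attempt to replicate digit-for-digit. The default engine pools the
residual variance across strata; `engine = "glmmTMB"` frees a per-stratum
residual variance (`dispformula`) at the cost of Wald $z$ tests instead of
Satterthwaite $t$ tests — and of `NA` standard errors whenever a variance
component lands on the zero boundary, where the Hessian is singular; its
point estimates and variance components remain usable. Variance-component significance uses
`lrt_variance()`: twice the REML log-likelihood gap against
$\chi^2_{\Delta k}$, with the 50:50 boundary mixture available behind a
flag (the plain $\chi^2$ is the default and is conservative).

## The synthetic-data generator and its calibration

`simulate_experiment()` emulates the assay: per MA subline a Poisson number
of fixed mutational events; genotypic fitness $g$ combining effects
additively ($1 - \sum s_i$, floored at 0; the default, because it keeps the
moment identities below exact) or multiplicatively ($\prod(1-s_i)$);
control pseudolines with $g = 1$; a mean-1 environmental multiplier
(lognormal by default, normal-additive behind a flag) with variance `v_e`;
a genotype-independent non-reproducer probability (a genotype-linked
variant exists for stress-testing the $w=0$ rule); and integer daily counts
(Poisson, or negative-binomial via the `overdispersion` knob) allocated
over days by `day_fractions`.

**Calibration.** The generator is parameterized on the scale of the
Bateman–Mukai estimators: `u` and the effect model are the values the
estimator pair converges to in the equal-effects case. For a compound
Poisson process with event rate $m$ and genotypic effect $s$, the pipeline
converges to $\Delta M = -ms$, $V_M = ms^2/2$, hence $U_{MIN} = 4m$ and
$E[a]_{MAX} = -s/4$: the estimators' diploid bookkeeping (the factors 2 in
$V_M = \Delta V_L/2t$ and $U_{MIN} = 2\Delta M^2/V_M$) compresses rate and
effect by exactly 4. Moment-matching therefore fixes the event rate at
$u/4$ and the genotypic effect at $4\times$ the drawn effect, so that
$E[\Delta \hat M] = -u\,E[a]$, $E[\hat V_M] = 2u\,E[a^2]$, and the plug-in
estimators recover $(u, -E[a])$ exactly under equal effects — and exhibit
the documented downward/upward biases under gamma-distributed effects
($U_{MIN} \to u\,E[a]^2/E[a^2]$, $E[a]_{MAX} \to -E[a^2]/E[a]$).
`expected_moments()` returns these pipeline-scale expectations, which is
what the recovery tests compare against.

**Defaults = study conditions** (chosen once, not tuned): $u = 0.02$,
equal effects $a = 0.05$, $t = 150$; 10 lines (5 high-, 5 low-fitness
labels), 10 pseudolines and 22 MA sublines per line, 5 replicates each;
ancestral mean output 148.5 offspring; day fractions $(0.55, 0.35, 0.10)$,
an early-peaked hermaphrodite schedule; `v_e = 0.4` plus a 0.05
non-reproducer probability, which together put the within-subline variance
of $w^*$ near 0.5 — the scale observed in real worm assays of this design.

**What the generator does *not* emulate:** within-lineage fixation dynamics
(mutation accumulation is collapsed to an effective fixed-event rate),
selection during MA beyond the crude `neutrality_threshold` thinning knob,
assay mortality (survival indicators are all-true; the $l_x m_x$ product
enters through zero counts), block/plate effects, and any genotype-by-
environment structure. Passing recovery tests therefore demonstrates that
the *estimators* are implemented correctly and behave as theory predicts
under the model's assumptions — not that real assay data meet those
assumptions.

## Numerical and degenerate-input conventions

- Components are truncated at zero before differencing, and the $V_M$
  difference is floored at zero afterwards. Both truncations bias $V_M$
  slightly downward (of order 10–20% at 10–24 sublines with realistic
  noise); the recovery tests account for this explicitly rather than
  pretending the estimator is unbiased at small $n$.
- Zero total variance in a stratum returns components $(0, 0)$ with a
  warning; a single subline is an error.
- Undefined Bateman–Mukai values propagate as flagged `NA`, and group
  summaries drop them (a quantity undefined for a whole group summarizes
  to `NA`, not an error).
- A dead-on-day encoding: a worm dead on day $d$ has count 0 and survival
  `FALSE`; a *missing* count on a survived day is a validation error.
  Validation reports every offending row by number and never drops rows
  silently.
- Percentile CIs use the empirical quantiles (type 7) of the stored
  resample vector; ties and zero-width intervals are legitimate outputs on
  degenerate data.

## Problem sizes used by the test suite

Simulation-based checks are sized to run in seconds while keeping their
statistical claims honest (binomial slack is stated next to each
threshold): hierarchical-model type-I and coverage checks use 40
experiments of 4 lines × (4 + 6) sublines × 3 replicates; LRT power uses
60 datasets of 20 sublines × 5; the REML boundary-null check uses 200
datasets of 5 pseudolines × 20; full-design recovery of the generator's
moments uses 40 experiments of 100 sublines × 10; and the Bateman–Mukai
recovery check uses 200 experiments per effect model at the assay-scale
design (24 MA sublines, 10 pseudolines, 5 replicates), summarized by
medians with bootstrap standard errors, for the heavy-tail reasons above.

## Known limitations

- The normal-theory REML machinery is applied to $w$, which is
  non-negative and zero-inflated; this mirrors standard practice for these
  assays but is a model misspecification, and the bootstrap (which does not
  assume normality) is the primary uncertainty statement.
- Satterthwaite df are not a digit-for-digit replacement for other
  software's Kenward–Roger adjustments; small-sample fixed-effect $p$
  values can differ in the second decimal.
- $U_{MIN}$/$E[a]_{MAX}$ inherit every caveat of moment-ratio estimators:
  heavy tails, negative sampling covariance between the pair, and
  confounding of rate with effect size. Medians across lines, not means,
  are the robust summary.
- The pipeline estimates *effective* mutational parameters for fitness; it
  has no sequence-level information and cannot separate mutation rate from
  effect-size changes.
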