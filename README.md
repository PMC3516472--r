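# mutacc

Analysis of mutation-accumulation (MA) fitness assays in R.

MA experiments propagate replicate lineages at minimal population size so
that selection is ineffective and spontaneous mutations accumulate nearly
neutrally; comparing the descendant lines with their cryopreserved ancestor
measures the rate and effects of new deleterious mutations. `mutacc`
implements the full estimation pipeline for a nested second-order MA design
(first-order line → subline → replicate worm), from per-worm daily offspring
counts to:

- **Demographic relative fitness.** Absolute fitness *W* is a worm's lifetime
  reproductive output. Relative fitness is the discounted sum
  *w* = Σ<sub>x</sub> e<sup>−r₀x</sup> l<sub>x</sub>m<sub>x</sub>, where
  l<sub>x</sub>m<sub>x</sub> is the survivorship × fecundity product at age
  *x* and *r₀* solves the Euler–Lotka-type equation
  Σ<sub>x</sub> e<sup>−r₀x</sup> l̄<sub>x</sub>m̄<sub>x</sub> = 1 on the mean
  control schedule, so the control mean *w* is 1 by construction. One *r₀*
  per assay; non-reproducers have *w* = 0.
- **Mutational decay of the mean.** ΔM<sub>w</sub> = (w̄<sub>MA</sub> − 1)/*t*
  per generation, with *t* the generations of MA.
- **Mutational variance.** V<sub>M</sub> = max(0, (V<sub>L,MA</sub> −
  V<sub>L,0</sub>)/2*t*) from among-subline variance components (method of
  moments or REML), on the ancestral-mean scale and on the own-group-mean
  ("opportunity for selection") scale V<sub>M*</sub>; mutational
  heritability h²<sub>M</sub> = V<sub>M*</sub>/V̄<sub>E*</sub>.
- **Bateman–Mukai bounds.** U<sub>MIN</sub> = 2ΔM²/V<sub>M</sub> (genomic
  mutation rate, biased down) and E[a]<sub>MAX</sub> = V<sub>M</sub>/2ΔM
  (mean effect, biased up), flagged undefined when ΔM ≥ 0.
- **Uncertainty.** A subline-level bootstrap (all replicates of a drawn
  subline resampled together, control and MA strata separately) gives point
  estimates as bootstrap means and percentile confidence intervals;
  Bateman–Mukai parameters are computed from the bootstrap means.
- **Group comparison.** A hierarchical mixed model of *w* on Gmax with a
  Gmax × fitness-group interaction, per-stratum among-subline variance
  components, and likelihood-ratio tests for variance components.
- **A calibrated synthetic-data generator** (`simulate_experiment()`) that
  emulates the whole nested design, so every stage of the pipeline can be
  validated by parameter recovery without any external data.

## Worked example

Simulate a small experiment with known truth (genomic rate U = 0.02, every
mutation reducing relative fitness by a = 0.05) and run the pipeline:

```r
library(mutacc)

params <- sim_params(u = 0.02, effect = effect_equal(0.05), n_lines = 4,
                     n_sublines = 12, n_pseudolines = 8)
sim <- simulate_experiment(params, seed = 42)
res <- run_ma_pipeline(sim$table, settings = bootstrap_settings(1000),
                       seed = 1, hierarchical = FALSE)
res
#> MA pipeline: 1 assay(s), 400 worms, t = 150, 1000 bootstrap reps
#>
#> r0 per assay:
#>   assay_id    r0 residual
#> 1 sim      0.944        0
#>
#> Per-line estimates:
#>   assay_id line_id fitness_class wbar_ma   delta_m  v_m_star   u_min e_a_max
#> 1 sim      L01     high            0.865 -0.00119  0.000334  0.0110  -0.108
#> 2 sim      L02     high            0.772 -0.00136  0.000297  0.0235  -0.0576
#> 3 sim      L03     low             0.886 -0.000454 0.0000336 0.0174  -0.0261
#> 4 sim      L04     low             0.907 -0.000557 0.000240  0.00323 -0.172
```

`r0 = 0.944`/day is the control intrinsic rate of increase (about 150
offspring discounted over days 4.75–6.75). Each line's MA sublines declined
to a mean relative fitness `wbar_ma` of 0.77–0.91 after 150 generations,
i.e. decay rates `delta_m` of −0.5 to −1.4 × 10⁻³ per generation around the
simulated truth −u·a = −1 × 10⁻³; `u_min` and `e_a_max` are the per-line
Bateman–Mukai bounds (noisy at this deliberately small design size, tight
at the full one). Published per-line summaries can be checked directly:

```r
bateman_mukai(-2.84e-3, 1.84e-4)
#>    delta_m      v_m  u_min e_a_max defined note
#> 1 -0.00284 0.000184 0.0877 -0.0324 TRUE    <NA>

exact_rank_probability(5, 5, 3)   # 3 fastest-declining lines all low-fitness
#> 0.08333333
```

Assay tables are plain CSV/TSV (`read_assay_table()` /
`write_assay_table()`, configurable headers via `assay_cols()`); a small
synthetic example ships in `inst/extdata/example_assay_synthetic.csv`. A
thin command-line wrapper with `simulate` and `analyze` subcommands lives
in `inst/cli/ma-pipeline.R`.

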