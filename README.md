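# ctdnakin

Mechanistic modeling of early treatment response in acute myeloid
leukemia (AML) from circulating tumor DNA (ctDNA).

## Who this is for

During induction chemotherapy, AML response is assessed by a second
bone-marrow biopsy at day 16–21 that counts residual leukemic blasts.
ctDNA — the mutation-bearing fraction of cell-free DNA in peripheral
blood — offers a needle-free alternative, but its relationship to marrow
blast kinetics is indirect. `ctdnakin` is for quantitative scientists who
want to (a) fit compartmental models linking blast death to peripheral
ctDNA across a patient cohort, (b) predict a patient's marrow blast burden
from blood draws alone, and (c) study the mutation fraction α as a relapse
signal — on real cohort files or on a bundled synthetic-cohort generator
with retained ground truth.

## The model

Three nested linear compartment models are provided; the headline
**three-step model** is

    dB/dt   = -γ_d B          (blasts die in the marrow)
    dc_bm/dt = γ_d B - γ_t c_bm   (their ctDNA pools in the marrow)
    dc_pb/dt = γ_t c_bm - γ_deg c_pb  (transits to blood, degrades)

with observables `y_ctdna = α·c_pb` (the assayed-mutation fraction of
ctDNA) and `y_blast = B`; `γ_deg = 33/day` is fixed (30-min half-life) and
`c_bm(0) = (γ_deg/γ_t)·c_pb(0)·s_c`, `s_c ≥ 1`, keeps the blood ctDNA
gradient non-negative at treatment start. Patient heterogeneity is modeled
as log-normal random effects `φ = Aβ + Bb`, `b ~ N(0, exp(diag(δ)))`, and
the population is estimated by a first-order conditional (Laplace)
marginal likelihood with multi-start local optimization (compiled inner
Gauss–Newton; closed-form solutions and sensitivities via confluent
divided differences, uniformly stable across all rate degeneracies).

## Worked example

```r
library(ctdnakin)

sim  <- simulate_cohort(clinical_defaults(seed = 1))  # 10 patients
prep <- prepare_cohort(sim$cohort)                      # counts + noise sds
fit  <- fit_population(prep, "three_step", fit_config(n_starts = 10, seed = 1))
print(fit)
#> <population_estimate> three_step
#>   log-likelihood: -459.5288
#>   typical values (natural scale):
#>     B0       9.009e+11
#>     c0pb     7.661e+05
#>     gamma_d  0.4989
#>     s_c      1.736
#>     alpha    0.1125
#>     gamma_t  4.905
#>   random-effect sds (transformed scale):
#>     B0       0.152
#>     c0pb     0.611
#>     gamma_d  0.289
#>     s_c      0.262
#>     alpha    1.118
#>   sigma_c:0.1041656 (log10 scale)
#>   multistart: 10/10 converged; top objectives -459.5288, -459.5560, -460.5458
```

The typical values are the natural-scale population parameters (initial
blast count ~9e11 of 1.2e12 nucleated marrow cells, blast death rate
~0.5/day, marrow-to-blood transit ~5/day); the random-effect sds are
patient-to-patient log-scale variability; the waterfall line shows all 10
starts converging to the same optimum — the generating values here were
B0 = 9e11, c0pb = 1e6, γ_d = 0.5, s_c = 2, α = 0.2, γ_t = 3.

Single-patient estimates against the population prior, and the α relapse
report:

```r
ests <- lapply(prep, estimate_single_patient, population = fit)
rel  <- vapply(prep, `[[`, TRUE, "relapse")
print(alpha_relapse_report(ests, rel))
#> <alpha_report>
#>  patient_id      alpha relapse
#>         S01 0.13729313   FALSE
#>         ...
#>         S04 0.03290657    TRUE
#>         S07 0.02436023    TRUE
#>         S09 0.02038776    TRUE
#>         ...
#>   pair separation (alpha_relapsed < alpha_non-relapsed): 1.00
```

The three simulated relapse patients (generated with α shrunk 10×,
emulating additional unassayed leukemic clones) have the three smallest
estimated α — every relapsed/non-relapsed pair is correctly ordered.

Identifiability diagnostics reproduce the structural facts: with blasts
and ctDNA observed the two- and three-step models are identifiable; from
ctDNA alone the three-step model loses exactly the
`(B0, c0pb) vs α` scaling mode:

```r
print(fim_rank_analysis("three_step", fit$typical_values, "y_ctdna"))
#> <identifiability_report> three_step observing y_ctdna
#>   rank 5 of 6 -> rank_deficient
#>   null direction(s) in log-parameter space:
#>            [,1]
#>  B0      -0.5774
#>  c0pb    -0.5774
#>  alpha    0.5774
#>  ...
```

Leave-one-out blast prediction from ctDNA alone
(`loo_predict_blasts(prep, "three_step", fit_config(fast = TRUE))`)
re-fits the population without each patient and reports per-measurement
relative errors and within-10% flags. Note the structural bound discussed
in the methods vignette: from ctDNA alone, day-0 blast accuracy is limited
by the population prior through the scaling null mode.

A command-line front end with `simulate | fit | identify | report`
subcommands is installed at `inst/cli/ctdnakin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ctdnakin.R", package="ctdnakin"))')" \
    simulate --out run1 --seed 1
```

## Layout

- `R/`, `src/` — implementation (kinetics, cohort I/O and preprocessing,
  population fit, patient inference, identifiability, synthetic cohorts,
  pipeline); compiled core in `src/kinetics.cpp`.
- `vignettes/ctdnakin-methods.Rmd` — model, assumptions, numerical
  choices, generator rationale, known limitations.
- `tests/testthat/` — unit and property tests plus `test-acceptance.R`.
- `inst/extdata/clinical_table_patients.csv` — published covariates and
  measurement counts of the 10-patient clinical cohort (values are not
  published; `clinical_reference_cohort()` builds a labeled stand-in).
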