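# sivar

Model-based insulin sensitivity (SI) and its hour-to-hour variability in
critical-care glycaemic control.

## The problem

Blood glucose (BG) level and variability in the ICU are strongly associated
with mortality, but association is not mechanism: are patients who die
metabolically *harder to control* (lower insulin sensitivity, more
hour-to-hour variability), or are survivors and non-survivors equally
controllable, so that glycaemic outcome mostly reflects the quality of the
control delivered? Answering this requires a patient-specific, model-based
measure of metabolic state identified from routinely collected
BG/insulin/nutrition data — and both *difference* testing and *equivalence*
testing between outcome groups.

`sivar` is aimed at researchers analysing glycaemic-control time series (or
designing GC studies) who need that machinery as tested, reproducible code.

## What it implements

* **Model core** — a three-compartment glucose–insulin kinetic model of the
  ICING family,

  $$\dot G = -p_G G - S_I G \tfrac{Q}{1+\alpha_G Q} + \tfrac{P + EGP - CNS}{V_G},
  \qquad
  \dot Q = n_I(I-Q) - n_C \tfrac{Q}{1+\alpha_G Q},$$

  with saturable hepatic/renal insulin clearances and bounded endogenous
  secretion, simulated with an adaptive stiff-capable solver that restarts at
  every piecewise-constant input or SI step (`simulate_icing()`).
* **Hourly SI identification** by the integral method: the insulin
  compartments are SI-free and simulated once, after which integrating the
  glucose equation over each therapy-anchored hour yields a closed-form
  linear solve for SI (`fit_si_profile()`).
* **Variability statistic** — the forward hour-to-hour percentage change
  %ΔSIᵢ = 100 × (SIᵢ₊₁ − SIᵢ)/SIᵢ, pooled with SI into twelve 6-h blocks per
  72 h by outcome group, with empirical CDFs (`compute_delta_si()`,
  `pool_blocks()`).
* **Statistics** — percentile-bootstrap CIs (95% and Bonferroni-consistent
  99.6%) for differences of medians, two-sample Kolmogorov–Smirnov tests,
  and clinical-equivalence testing against a measurement-error-derived range:
  the relative SI change needed to exceed a 9.4%-SD BG measurement error,
  about ±13% at 6 mmol/L and BG-dependent (`bootstrap_median_diff()`,
  `derive_equivalence_range()`, `compare_block()`).
* **Virtual-patient generator** — lognormal mean-reverting hourly SI
  dynamics with a configurable group offset, a stylised insulin+nutrition
  feedback protocol, multiplicative BG measurement error and length-of-stay
  dropout, so the whole pipeline is testable against known truth
  (`generate_cohort()`).
* **Pipeline** — cohort selection (therapy started ≤ 12 h from admission;
  ≥ 24 h data for cohort 1, ≥ 72 h for the dropout-sensitivity cohort 2),
  end-to-end analysis and CSV/text reporting (`select_cohort()`,
  `run_analysis()`, `render_report()`), plus a thin CLI at
  `inst/scripts/sivar-pipeline.R` with `simulate`/`identify`/`analyse`
  subcommands.

## Worked example

```r
library(sivar)
params <- default_icing_params()

## a virtual cohort with the structure of a tightly controlled ICU:
## non-survivor SI 20% higher, shared variability, 9.4% BG measurement error
cfg <- cohort_config(n_survivors = 119, n_nonsurvivors = 26, seed = 20256)
cohort <- generate_cohort(cfg, params)

res <- run_analysis(cohort$records, params, n_boot = 1000, seed = 20256,
                    cohorts = "cohort1")
print(res)
#> cohort1: 129 included, 16 excluded
#>   si       equivalent 0/12 blocks, significant (95%) 5, after Bonferroni 3
#>   delta_si equivalent 12/12 blocks, significant (95%) 0, after Bonferroni 0
#>   BG percent diff 3.4 [0.6, 5.5]%: equivalent
```

Reading this output: 16 virtual patients dropped out before 24 h of therapy
and are excluded from cohort 1. SI *level* differs between the groups beyond
the measurement-error equivalence range in all 12 six-hour blocks (and is
statistically significant in 5), while the hour-to-hour variability %ΔSI is
clinically equivalent in all 12 blocks and never significantly different —
the two groups differ in level, not in controllability. The whole-cohort
median BG difference (3.4%) is well inside the ±9.4% measurement-error range:
clinically equivalent control.

Individual pieces are available directly:

```r
rng <- derive_equivalence_range(params, bg_error_sd = 9.4, reference_bg = 6)
print(rng)
#> equivalence half-width: +/-13.4% (BG 6 mmol/L, 9.4% BG error, threshold)

prof <- fit_si_profile(cohort$records[[1]], params)
head(prof, 3)
#>   patient_id hour           si    flag
#> 1       S001    0 1.591385e-04      ok
#> 2       S001    1 6.496725e-05      ok
#> 3       S001    2 1.000000e-08 clamped
```

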