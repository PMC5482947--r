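---
title: "Model-based insulin sensitivity and its hour-to-hour variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based insulin sensitivity and its hour-to-hour variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sivar)
```

## The scientific question

In intensive-care glycaemic control (GC), blood glucose (BG) level and
variability are strongly associated with mortality. Two competing readings of
that association exist: either sicker patients are metabolically *harder to
control* (lower insulin sensitivity, more hour-to-hour metabolic variability),
so patient condition drives glycaemia and outcome; or patients who live and
die are equally controllable, and glycaemic outcome mostly reflects the
quality of the control delivered. `sivar` implements the model-based machinery
needed to ask this question of clinical-style BG/insulin/nutrition records:
hourly insulin sensitivity (SI) identification from a physiological model, a
variability statistic, and difference *and* equivalence testing between
outcome groups in 6-hour blocks — plus a virtual-patient generator so that the
whole pipeline can be validated end to end against known ground truth.

## The glucose–insulin model

The model is a three-compartment glucose–insulin kinetic model of the ICING
(Intensive Control Insulin-Nutrition-Glucose) family:

$$\dot G = -p_G G - S_I\, G \frac{Q}{1+\alpha_G Q}
          + \frac{P(t) + EGP - CNS}{V_G}$$
$$\dot I = -n_K I - \frac{n_L I}{1+\alpha_I I} - n_I (I - Q)
          + \frac{u_{ex}(t)}{V_I} + (1-x_L)\frac{u_{en}(G)}{V_I}$$
$$\dot Q = n_I (I - Q) - n_C \frac{Q}{1+\alpha_G Q}$$

with $G$ blood glucose (mmol/L), $I$ plasma and $Q$ interstitial insulin
(mU/L), $P$ dextrose appearance (mmol/min), $u_{ex}$ exogenous insulin
(mU/min) and $u_{en}(G)$ endogenous secretion (mU/min). $S_I$ (L/mU/min) is
the patient-specific, hour-to-hour time-varying parameter of interest: it
scales saturable insulin-mediated glucose disposal.

Two modelling points deserve comment:

* **Sign of the renal clearance term.** Some typesettings of the plasma
  insulin equation show the $n_K I$ term with a positive sign. Physiologically
  it is a clearance, and we implement it as a loss; the
  `printed_nk_sign` parameter flag restores the positive sign for audit.
* **Endogenous secretion.** We use a bounded saturating-linear form
  $u_{en}(G) = \min(u_{max}, \max(u_{basal}, k_1 G + k_2))$, chosen because
  secretion must be a bounded non-decreasing function of glucose; setting the
  bounds to zero represents fully suppressed secretion. All constants
  (including the secretion model) are configuration with literature defaults
  shipped in `extdata/icing_defaults.json`; nothing is hard-coded in the
  computations.

Forward simulation (`simulate_icing()`) uses a stiff-capable adaptive solver
(`deSolve::lsoda`, `rtol = 1e-6`, `atol = 1e-8`) and restarts the integration
at every discontinuity of the piecewise-constant inputs and of the hourly SI
trajectory, so steps are honoured exactly. The tolerances were chosen so that
the identification error is dominated by the data, not the integrator; the
test suite verifies agreement with a 0.01-min explicit-Euler oracle to a
relative error below $10^{-4}$.

## Hourly SI identification by the integral method

The insulin equations do not involve $S_I$, so the insulin compartments can be
simulated once per record, driven by the measured (interpolated) BG through
$u_{en}(G)$ — this keeps the subsequent solve linear. Integrating the glucose
equation over a therapy-anchored hour $[h, h+1)$ then leaves SI as the only
unknown:

$$S_I = \frac{-\Delta G_h - p_G \int_h \hat G\,dt
        + \int_h \frac{P + EGP - CNS}{V_G}\,dt}
       {\int_h \hat G \frac{Q}{1+\alpha_G Q}\,dt}$$

Numerical conventions (fixed for reproducibility, since several are genuinely
open choices):

* BG is interpolated piecewise-linearly; integrals use the composite
  trapezoid on a 1-min grid; the nutrition integral is computed exactly from
  the step schedule.
* Hours are 0-based and half-open, anchored at therapy start; hours only
  partially covered by BG data at the record edges are dropped, never
  extrapolated.
* The insulin compartments are hot-started at the endogenous-only steady
  state for the first measured BG (a patient entering GC has typically not
  yet received IV insulin).
* A negative solution — possible under measurement noise — is clamped to
  `si_min = 1e-8` L/mU/min and flagged `clamped`, keeping the downstream
  variability statistic finite; SI is physiologically non-negative. A
  vanishing denominator (no effective insulin) is flagged `unidentifiable`
  and produces no value.

On noise-free synthetic records the solve recovers hourly SI with a median
absolute relative error of about 1% at hourly BG sampling and well below 1%
at 5-min sampling; the acceptance suite checks `< 5%` and `< 1%`
respectively, and cross-checks the closed form per hour against a brute-force
scalar minimisation of the end-of-hour glucose mismatch. Under multiplicative
BG measurement error the identified SI is median-unbiased; the suite verifies
this with a sign test on records perturbed at fixed inputs (perturbing inside
the closed control loop would conflate measurement error with the
controller's response to it).

## The variability statistic and block statistics

The forward hour-to-hour percentage change
$$\%\Delta SI_i = 100 \times \frac{SI_{i+1} - SI_i}{SI_i}$$
is the variability metric: it is scale-free (multiplying a profile by any
constant leaves it unchanged), so groups with different SI *levels* can still
be compared for *variability*. A change at hour $i$ is assigned to the 6-h
block containing $i$; SI values and changes are pooled across patients and
hours into twelve 6-h blocks per 72-h analysis, per outcome group, and
summarised as empirical CDFs, medians and IQRs.

Differences between groups are tested per block with:

* a percentile bootstrap (1000 resamples with replacement at the original
  group sizes) for the difference of medians, at 95% and at 99.6% — the
  latter consistent with a Bonferroni correction of $0.05/12 = 0.004$ for the
  twelve comparisons. We use the plain percentile interval rather than BCa
  for transparency; `n_boot` is configurable.
* the two-sample Kolmogorov–Smirnov test for bias and shape differences of
  the variability distributions.

## Equivalence testing and the measurement-error range

Statistical difference is not clinical significance: with many pooled values,
tiny differences become "significant". Equivalence testing asks the opposite
question — is the difference small enough to be clinically indistinguishable
from BG measurement error? The equivalence range is derived as *the relative
change in SI required to exceed BG measurement error*: a sustained relative
change $h$ in SI over one hour shifts that hour's glucose balance by
$h \cdot SI \cdot \int \hat G Q/(1+\alpha_G Q)\,dt$ mmol/L, so equating this
to the 1-SD error $\varepsilon G$ (with $\varepsilon$ = 9.4%, a typical
glucometer error SD) gives the half-width

$$h^\ast = \frac{100\,\varepsilon\, G}{-\Delta G - p_G\int \hat G\,dt
  + \int (P+EGP-CNS)/V_G\,dt}.$$

The numerator quantities are evaluated by actually running the hourly fit on
a self-consistent steady reference record (goal feed 6 g/h, insulin 3 U/h) at
the BG level of interest. The resulting half-width is about 13% at 6 mmol/L
and grows with BG (about 10% at 5, about 21% at 8 mmol/L), so the pipeline
derives a separate range per block at the block's observed median BG. A
perturb-and-refit variant (`method = "perturb"`, perturbing the boundary
measurements and re-running the fit) is provided for audit; it additionally
picks up interpolation side effects — the perturbed trace also moves the
$p_G\int\hat G$ term and the denominator — and is therefore systematically
wider, which is why the threshold form is the default.

A group difference is *equivalent* when the whole 95% bootstrap CI lies
inside $[-h^\ast, +h^\ast]$: the percent-difference CI for SI (level is
scale-dependent), the absolute-difference CI for $\%\Delta SI$ (already in
percent units). Equivalence and statistical difference are deliberately not
mutually exclusive. Whole-cohort BG is additionally tested against the raw
$\pm 9.4\%$ range.

## The virtual-patient generator

No clinical data ship with the package; the generator
(`generate_cohort()`) emulates the statistical structure the analysis
assumes, so every stage can be tested against known truth. Per patient:

* **True SI trajectory.** Log SI follows a mean-reverting multiplicative
  walk about a drifting group median:
  $a_{h+1} = \varphi a_h + \sigma_h \epsilon$, $SI_h = e^{\mu_h + a_h}$
  truncated to $[10^{-6}, 5\times10^{-3}]$ L/mU/min. Defaults: survivor
  median $1.5\times10^{-4}$ rising by a factor 1.35/day (patients recover
  sensitivity), non-survivor median 20% higher with *shared* variability,
  hour-to-hour step SD falling from 40% to 8% across 72 h, initial
  between-patient dispersion 0.9 (log scale), $\varphi = 0.95$/h. A pure
  geometric random walk was rejected because its between-patient dispersion
  grows without bound, whereas stabilising ICU cohorts show block IQRs that
  *narrow* over the stay; mean reversion with a decaying step SD reproduces
  both the wide, right-skewed early distributions and the narrowing, while
  remaining lognormal and positive. The initial-dispersion parameter exists
  for the same reason: early-block spread in real cohorts is dominated by
  who the patients are, not by how they move hour to hour.
* **Closed-loop control.** A stylised, deterministic, quantised
  insulin-plus-nutrition protocol stands in for table-based GC protocols
  (whose literal look-up tables are not public): insulin steps up above the
  4.4–8.0 mmol/L band (faster when BG is rising, earlier when above
  6.5 mmol/L), caps at 6 U/h, backs off on fast falls and stops below band;
  feed steps down through fixed fractions of a 6 g/h goal under sustained
  hyperglycaemia. Under the defaults the simulated cohorts land near a
  median insulin of 3 U/h, median feed near 4 g/h and a cohort median BG
  inside the band — the operating point typical of tightly controlled ICU
  cohorts.
* **Measurement and dropout.** BG is sampled every 90 min (about 16
  measurements/day) with multiplicative Gaussian error (SD 9.4%, truncated
  at 3 SD); therapy starts uniformly within 12 h of admission; therapy
  duration is lognormal (median 80 h), so roughly half the cohort reaches
  72 h — which is what the cohort-2 (≥ 72 h) sensitivity rule is for.

What the generator does *not* emulate: real comorbidity structure, any
dependence between SI level and length of stay (treated as independent),
sensor drift, non-glucose covariates. Passing tests therefore demonstrate
that the pipeline's numerics and statistics behave correctly under the
assumed structure, not that the structure is a fit to any particular ICU.

## Statistical calibration and a known limitation

Under a null configuration (no group offset, shared variability), the
pipeline's bootstrap 95% CIs for the $\%\Delta SI$ difference of medians
exclude zero at about the nominal 5% rate, and the per-block KS p values are
approximately uniform — $\%\Delta SI$ values are dominated by the
hour-to-hour innovations and are close to exchangeable across patients and
hours (consecutive changes share an endpoint and are mildly negatively
correlated, which makes the checks slightly conservative).

The SI *level* metric is different: each patient contributes six strongly
correlated hourly values per block, and when between-patient dispersion
dominates, resampling pooled values as iid understates the sampling
variability of the pooled median (the effective sample size is closer to the
number of patients than to the number of values). Block-level CIs for SI
level are therefore anti-conservative under the pooled design — a property
of the pooled-bootstrap design itself, which the package reproduces
faithfully because comparability with the established analysis is the point.
Consequently null calibration is asserted for the variability metric, where
the design is sound; SI-level CIs should be read as descriptive of the
pooled distributions.

## Problem sizes used by the tests

The suite exercises the pipeline at sizes chosen to make the Monte-Carlo
bands tight enough to be meaningful while keeping a single-CPU run
comfortable: 100 noise-free virtual patients for parameter recovery, ten
null cohorts of 30 + 30 for calibration (120 block comparisons), and one
structured cohort at the study-like 119 + 26 split for the headline
qualitative check (SI level not equivalent in at least 10 of 12 blocks,
variability equivalent in at least 10 of 12). `scripts/acceptance.R` re-runs
the same computations at moderately reduced sizes and writes the resulting
numbers as JSON.

## Known limitations

* SI is the only time-varying identified parameter; all other constants are
  population defaults, so identified SI absorbs any patient-specific
  deviation in them. This matches the metric's established use; it is a
  relative, not absolute, sensitivity measure.
* The equivalence range is a re-derivation from the stated definition
  (SI change needed to exceed measurement error) at a fixed reference
  operating point; it is an approximation, not a replica of any particular
  published supplementary calculation.
* The hourly solve assumes BG coverage of the whole hour and piecewise-linear
  BG between measurements; at sampling sparser than ~2 h the interpolation
  error grows and hours without coverage are simply absent.
* Records are assumed to start at (or before) meaningful insulin exposure;
  the endogenous-only hot start is wrong for a patient transferred
  mid-infusion, in which case the first hour or two of identified SI should
  be discarded.
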