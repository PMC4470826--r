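---
title: "Comparing GFR estimating equations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing GFR estimating equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfragree)
```

## The problem

Glomerular filtration rate (GFR) is rarely measured directly; clinical
practice estimates it from serum biomarkers. Creatinine-based equations
(Cockcroft-Gault, MDRD-4, CKD-EPI) are standard because creatinine assays are
cheap and internationally calibrated, but creatinine also reflects muscle
mass and nutrition. Cystatin C, produced at a near-constant rate and largely
independent of body composition, is a better filtration marker but too
expensive for routine use in much of sub-Saharan Africa. In a population
where HIV infection is prevalent — and systematically lowers body-mass index
and muscle mass — a creatinine equation can be biased in exactly the group
where kidney disease is most consequential. This package provides the
machinery to quantify that: evaluate every equation variant, measure pairwise
agreement with cystatin C as the reference, and translate disagreement into
chronic kidney disease (CKD) stage misclassification.

## Equations and the black-American factor

Nine equation variants are implemented (`egfr_equations()`), all taking
creatinine in mg/dL, cystatin C in mg/L, weight in kg, age in years as a real
number (no truncation; no rounding convention is imposed).

Two deliberate unit/semantics choices:

- **Cockcroft-Gault returns raw creatinine clearance in mL/min**, not a
  body-surface-area-indexed value — the formula has no BSA term, and the
  comparison literature compares it directly to indexed eGFRs. The panel
  records the unit per column (`attr(panel, "units")`) so the mismatch is
  explicit, never silent.
- **The black-American factor is an analysis switch, not a subject field.**
  The multiplicative factors (1.212 in MDRD-4, 166/144 and 163/141 in
  CKD-EPI, 1.06 in CKD-EPI cystatin C full) were derived in US cohorts; in an
  ethnically homogeneous African cohort the scientific question is whether
  the factor should apply to *everyone or no one*, so each factored equation
  is simply a separate panel column (`mdrd4` vs `mdrd4_black`, etc.).

The CKD-EPI creatinine equation is piecewise in creatinine with a
sex-specific knot (0.7 mg/dL female, 0.9 male); both branches evaluate to the
same value at the knot, and the test suite asserts continuity to 1e-4 as well
as agreement of every variant with an independent one-line re-implementation
to 1e-9 relative error.

## Bland-Altman agreement with modelled limits

For an ordered pair of methods, A the first-named reference, the per-subject
difference is d = A − B and the abscissa m = (A + B)/2; d < 0 means B
overestimates the reference. Three limits-of-agreement (LoA) constructions
are available, each computed independently per stratum (typically HIV
status):

1. **Classic** (`ba_classic`): d̂ = mean(d), LoA = d̂ ± 2·sd(d).
2. **Linear-regression** (`ba_regression`), the default: eGFR differences are
   typically heteroscedastic — spread shrinks at higher mean eGFR — so the
   mean difference is fitted as d̂(m) = β₀ + β₁m, and the scale from a second
   regression of the absolute residuals on m. For a normal residual
   E|r| = σ√(2/π), so σ̂(m) = √(π/2)·(γ₀ + γ₁m), and LoA = d̂(m) ± 2σ̂(m).
   With β₁ = 0 and constant spread this reproduces the classic band (a
   property test checks it to within Monte-Carlo error).
3. **Quantile-regression** (`ba_quantile`): linear quantile fits of d on m at
   τ = 0.025, 0.5, 0.975 (via `quantreg::rq`), preferred when the differences
   are strongly non-normal or the two methods' distributions differ in shape.
   The choice between 2 and 3 is a per-comparison user flag, not an automatic
   trigger: no principled numeric threshold exists for "strong
   non-linearity", so the decision is left to the analyst.

Numerical choices: the multiplier is **2.0** ("two standard deviations"), with
1.96 available via `multiplier`/`loa_multiplier` for exact normal 95% limits
— the 2.0 band covers 95.45% of normal differences, well inside any
practical reading of "about 95%". Curves are evaluated on a 100-point
equally spaced grid spanning the observed m range per stratum; this grid is
the tidy CSV plot-data contract (`stratum, m, mean_diff, lower, upper,
method, n`). A fitted σ̂(m) that goes negative at a grid edge is clamped to 0
with a warning. Degenerate strata (zero variance in m) fall back to the
classic construction with a warning. Minimum stratum sizes: 3 (classic), 10
(regression), 50 (quantile — the τ = 0.025 fit needs populated tails).
`loa_coverage()` evaluates empirical band coverage by interpolating the
fitted curves at each subject's m (flat extrapolation at the edges).

## Concordance metrics

For each ordered pair and stratum (`concordance_table()` adds a pooled
"overall" row):

- **absolute bias** = mean(d), in mL/min/1.73 m²;
- **precision** = sd(d)/√n, the standard error of the differences;
- **relative bias** = 100·(mean(B) − mean(A))/mean(A). This is the mean
  shift scaled by the reference mean and therefore has the *opposite sign*
  to the absolute bias by construction — a predictor that overestimates the
  reference has negative mean difference but a positive percentage
  overestimate. Subgroup rows scale by the subgroup's own reference mean. A
  per-subject alternative (mean of 100·(b−a)/a) is available via
  `method = "per_subject"` for sensitivity analysis.
- **P10/P30 accuracy** = percentage of subjects with |a − b| ≤ margin·b,
  boundary inclusive; the margin is relative to the *second-named* method B.
  The orientation matters: "CKD-EPI vs cystatin C" accuracy asks what
  fraction of CKD-EPI values fall inside a cystatin-C-relative band, so the
  accuracy pair can legitimately be the reverse of the bias pair.

## CKD staging

Stages follow the standard five-band eGFR ladder (≥ 90, 60–89, 30–59, 15–29,
< 15 mL/min/1.73 m²), closed below and open above, so 60.0 is stage 2 —
matching the "< 60" definition of stage 3. Staging uses eGFR alone: no
albuminuria criterion is applied, so "stage 1" simply means eGFR ≥ 90, and
stage 3 is not split into 3a/3b. `stage_crosstab()` reports the full 5×5
cross-classification plus dichotomized counts at a cut-off stage k
(concordant, ≥ k by A only, ≥ k by B only; percentages always against the
total n).

## The synthetic cohort

`generate_cohort()` emulates the marginal structure of a Malawian adult
HIV-testing-centre population. Defaults (all overridable in
`cohort_params()`):

| parameter | default | note |
|---|---|---|
| n | 363 | study-sized cohort |
| HIV prevalence | 0.32 | |
| female fraction | 0.48 | |
| age | median 31, IQR 26–39, truncated ≥ 18 yr | log-normal, inverse-CDF truncation |
| creatinine (mg/dL) | HIV+ 0.69 (0.59–0.83); HIV− 0.74 (0.64–0.85) | log-normal per stratum |
| cystatin C (mg/L) | HIV+ 0.87 (0.78–0.98); HIV− 0.75 (0.67–0.84) | log-normal per stratum |
| BMI (kg/m²) | HIV+ 20.8 (19.0–22.9); HIV− 22.6 (20.9–26.2) | log-normal per stratum |
| log SCr–SCysC correlation ρ | 0.5 | Gaussian copula; not reported by any study, exposed as a parameter |
| CKD spike | 3% of subjects, both biomarkers × 2.5 | deliberate extrapolation |
| height | female N(1.57, 0.06²) m; male N(1.68, 0.07²) m | invented; only feeds weight = BMI·height² for Cockcroft-Gault |

Biomarkers are positive and right-skewed, and published summaries give only
median and IQR, so log-normal marginals are the natural choice:
`solve_lognormal()` sets μ = ln(median) and σ = ln(q3/q1)/(2·z₀.₇₅),
z₀.₇₅ = 0.6745. This preserves the median exactly and the IQR *ratio*
exactly; the individual quartile bounds coincide only when the published
quartiles are symmetric on the log scale (true for creatinine and
cystatin C, not for the HIV-negative BMI quartiles, whose lower spread is
about half the upper — a log-normal cannot reproduce both bounds, and the
tests assert median and IQR-ratio recovery accordingly).

The **CKD spike** deserves emphasis: the emulated population is young and
mostly healthy, so stages 3–5 would be nearly empty and the staging code
untestable. A small elevated component (3% of subjects with both biomarkers
multiplied by 2.5) populates the low-eGFR range while preserving realism. It
is a modelling convenience, not an epidemiological claim; parameter-recovery
tests therefore run with the spike disabled, since its whole purpose is to
perturb the marginal tails, and its effect is tested separately through stage
occupancy. Likewise the copula correlation is checked spike-free, because
multiplying *both* biomarkers of spike subjects induces extra dependence.

What the generator does **not** emulate: the real joint dependence of age,
BMI and biomarkers (all independent given HIV stratum here), assay noise,
ART-treatment effects, longitudinal trajectories, or any blood-pressure/
comorbidity structure. Passing tests on synthetic cohorts therefore
demonstrate that the *pipeline machinery* is correct under known conditions;
they do not validate the equations against any real population.

## Determinism and the report pipeline

`run_report()` drives the whole analysis (cohort → panel → descriptives →
concordance → staging → agreement curves) and writes a manifest sufficient
to reproduce the run exactly: a round-trip test rebuilds the configuration
from `manifest.json` alone and gets byte-identical outputs. All randomness
flows from a single integer seed through `withr::with_seed`, which also
leaves the caller's RNG state untouched. Cohort CSVs are written with 17
significant digits so doubles round-trip bit-exactly. A failure at any stage
removes partial outputs and raises a stage-named error.

Descriptive statistics use type-7 quantiles (linear interpolation between
order statistics; configurable, since published IQRs rarely state their
convention), Welch's t-test by default (the pooled-variance test is a flag),
and the χ² test without continuity correction by default (Yates' correction
is a flag) — the conventions most software defaults share.

## Problem sizes in the test suite

Simulation-based guarantees are tested at the sizes where their stated
tolerances are meaningful: LoA coverage and regression/classic equivalence
at n = 10⁴ pairs, σ-slope recovery within 10% at n = 10⁴, synthetic
parameter recovery within 1% (medians) at n = 10⁵, oracle agreement on 10³
random subjects. These sizes keep each property comfortably inside
Monte-Carlo error at the asserted tolerances while the full suite runs in
well under a minute.

## Known limitations

- Cystatin C is itself an imperfect GFR proxy; all "bias" here is relative
  to a chosen reference equation, not to measured GFR.
- Repeated-measures Bland-Altman and confidence intervals around the LoA
  lines are out of scope.
- Pediatric equations and the race-free CKD-EPI 2021 refits are not
  implemented.
- The quantile LoA uses linear quantile regression; strongly curved
  quantile structure would need spline terms the package does not expose.
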