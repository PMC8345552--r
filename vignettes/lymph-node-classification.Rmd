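---
title: "Comparing nodal classification systems: models, inference, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nodal classification systems: models, inference, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnstage)
```

## The scientific question

Nodal stage is among the strongest prognostic factors after curative
colorectal cancer resection, but the AJCC/UICC N category counts
positive nodes without reference to how many were examined. A sparse
harvest can understage a patient ("stage migration"); guidelines ask for
at least 12 examined nodes for that reason. Two families of
alternatives normalise by the harvest:

* the lymph node ratio `LNR = pLN / NELN`, and
* the log odds of positive nodes
  `LODDS = ln((pLN + 0.5)/(NELN − pLN + 0.5))`.

The 0.5 terms are the empirical-logistic continuity correction: LODDS is
finite at `pLN = 0` and `pLN = NELN`, precisely where LNR collapses all
patients to a single value regardless of harvest size. Both metrics are
continuous; clinical use needs cut-offs, and dozens of cut-off systems
have been published. This package implements the head-to-head comparison
of such interval classifications against the N category on a single
cohort, with honest inference for the difference in discrimination.

## The comparison procedure

For each subgroup analysed:

1. **Base model.** A Cox proportional-hazards model with six dichotomous
   covariates: age ≥ 70 years, male sex, tumour size at or above the
   analysis cohort's median (mm), poor differentiation (G3 + G4),
   advanced T (T3 + T4), rectal location. The size median is recomputed
   within each analysis cohort; whether the original analysis re-derived
   it per subgroup is not documented, so we state our convention and
   expose `size_median` as an argument for the other choice.
2. **Nodal models.** Each classification enters the base model as
   indicator contrasts against its lowest (reference) class; the
   N-category model (N0/N1/N2 indicators, first present category as
   reference) is the comparator.
3. **Discrimination.** Harrell's C on each model's linear predictor.
   Convention: higher score ⇒ higher risk ⇒ shorter expected survival.
   Pairs are comparable when the shorter observed time is a death; two
   deaths at the same recorded time are incomparable; a death tied in
   time with a censored subject counts, the death being the failure.
   Tied scores on a comparable pair score 1/2.
4. **ΔC inference.** For scheme model A versus N-category model B on the
   same subjects, the jackknife recomputes `d⁽⁻ⁱ⁾ = C_A⁽⁻ⁱ⁾ − C_B⁽⁻ⁱ⁾`
   for every deletion i and uses
   `var = ((n−1)/n) Σ (d⁽⁻ⁱ⁾ − d̄)²`. The 95% CI is `ΔC ± 1.96·SE` and
   the p-value is two-sided normal. The same leave-one-out machinery
   gives the CI on each single C. Internally the pairwise
   concordance/comparability matrices are built once per model, so each
   deletion is a row-sum subtraction and the whole jackknife is O(n²);
   the test suite verifies exact agreement with a naive
   recompute-everything oracle.
5. **Multiplicity.** Benjamini–Hochberg step-up FDR over the family of
   schemes compared against N within one subgroup. Subgroups are
   separate families; cross-subgroup pooling is deliberately not done.

Degenerate situations are surfaced, not hidden: a scheme class empty in
a subgroup is merged into the adjacent class with a note in the report;
a subgroup without deaths is skipped with a notice; suspected monotone
likelihood (complete separation, e.g. a two-patient extreme class in
which both die early) is flagged on the fit and echoed in the analysis
notes.

## Numerical conventions

* **Ties in the Cox fit**: Efron approximation (the default of the
  `survival` package, which also performed the original analysis);
  Breslow available. Convergence: relative partial-log-likelihood change
  below 1e−9, at most 50 Newton–Raphson iterations.
* **CIs**: Wald on the log-hazard scale, `exp(β ± 1.959964·SE)`.
* **Interval schemes**: classes are validated to be increasing,
  non-overlapping and gap-free, covering [0, 1] for LNR and all reals
  for LODDS; consecutive classes must claim their shared boundary
  exactly once. Two printed cut-off sets needed repair, recorded in the
  scheme's `repairs` field and surfaced by `print()`: a rounding gap
  (0.24, 0.25) in the Fortea-Sanchis LNR system closed as a 0.25
  boundary, and a sign slip in the Bagante LODDS system (">0.9" read as
  ">−0.9", without which (−0.9, 0.9] would belong to no class). User
  configs may close printed gaps only via an explicit
  `"repair": "extend_left"` directive.
* **Log base**: natural log throughout; the printed LODDS cut-offs
  (−3 … +3) are consistent with natural log at NELN ≤ 68. Some cited
  cut-off systems may have been derived on a log10 scale; scheme configs
  carry a `log_base` field so that assumption is explicit.
* **Quantile scheme**: cut points at the 25/50/75th percentiles of the
  analysis cohort's LODDS (linear interpolation between order
  statistics, R type 7), fitted once per analysis cohort — not refitted
  within subgroups. Non-distinct quantiles are an error, not a silent
  collapse.
* **Imputation**: single imputation; medians for continuous covariates
  (even counts: mean of the central pair), modal category for
  categoricals with ties broken towards the first level of the declared
  category order.
* **Landmark ROC**: cases are deaths by the horizon, controls are
  subjects followed beyond it, subjects censored before the horizon are
  excluded (no IPCW reweighting — a stated limitation, matching the
  plain ROC reported in this literature). Both the continuous metrics
  and each scheme's class index are scored, since the source material
  describes both usages.

## The synthetic cohort: a stated world

The study's patient-level data are not available, so the generator
emulates the published summary tables and is the package's test bed.
Its defaults are fixed once and are not tuning knobs:

* **Exact marginals** by largest-remainder allocation at n = 654: stage
  171/232/251, 364 male, 239 rectal (hence node-negative 403 = 61.6%),
  grade and neoadjuvant counts, and the published T-distribution within
  each stage — so stage, T and node counts are mutually consistent and
  `derive_stage()` reproduces the assignment.
* **Node counts**: NELN = 2 + NegBin(μ = 15.8, size = 4.5) clipped to
  68 (median 17, range 2–68); stage III pLN zero-truncated
  NegBin(μ = 2.2, size = 0.6) capped at NELN (median 2); one N1c record
  (tumor deposits, pLN = 0, stage III) exercises that code path.
* **Hazard**: constant baseline (exponential survival, matching the
  constant-hazard assumption of the original power statement) times
  `exp(lp)`, with the published adjusted hazard ratios as defaults (age
  ln 3.32, male ln 1.23, size ln 1.32, grade ln 1.69, T ln 1.43, rectum
  ln 1.46) plus a log-linear LODDS term of 0.4 per unit — chosen so the
  top-to-reference spread across a typical LODDS scheme (~3.5 units ⇒
  HR ≈ 4) sits in the range of the published class-wise hazard ratios.
  A `node_effect_type = "n_category"` world routes the nodal effect
  through N0/N1/N2 indicators instead: the null world for type-I-error
  testing of the comparison machinery, under which no scheme should
  systematically beat N.
* **Censoring**: administrative at 150 months (the stated complete
  follow-up) combined with uniform dropout over (0, 264) months — a
  proxy for staggered accrual over the 22-year recruitment window. The
  baseline rate 0.00331/month was calibrated once (dev-time grid over
  100 seeds) so the default world realises ≈ 252 deaths per 654
  subjects, the published event count; `simulate_event_fraction()`
  rechecks this.

What the generator does **not** emulate: joint covariate dependence
beyond stage×T (age, sex, grade, size and location are drawn
independently), the real cohort's censoring pattern, adjuvant-therapy
effects, and any cohort-specific structure behind the published
class-wise hazard ratios. A green test therefore establishes that the
*machinery* is correct and calibrated under a proportional-hazards
world with the published marginals — it does not reproduce the
cohort-dependent Table values, which is impossible without the data.

## Design choices where the source was open

* **Recovery testing and non-collapsibility.** Cox hazard ratios are
  non-collapsible: omitting even an independent prognostic covariate
  attenuates the others. Since the default world includes a LODDS term,
  the parameter-recovery check refits the *generating* model (base
  covariates + continuous LODDS, via `fit_base_model(extra = "lodds")`)
  at n = 20 000, recovering every true log-hazard within ±0.05; the
  six-covariate base model alone is additionally shown unbiased in a
  world generated without a node effect.
* **Sample-size formula.** `logrank_power()` implements the standard
  Schoenfeld events formula,
  `D = (z₁₋α/₂ + z₁₋β)² / (p(1−p) ln²HR)`, giving 256 events for
  HR 1.5, α 0.05, power 0.90, equal allocation. The originally printed
  420/210 statement is not derivable from these inputs by the classical
  formula (its accrual/follow-up assumptions were not stated); the
  discrepancy is documented rather than imitated.
* **Exclusion tally.** Whether the original exclusion categories
  overlapped is unstated; a record with several exclusion flags is
  counted once under the earliest criterion in the listed order, so the
  retained count plus the tally always partitions the input.
* **Empty classes** are merged into the adjacent class (keeping
  subjects) rather than dropped; every merge is reported.

## Limitations

* No proportionality diagnostics, time-varying effects, stratified or
  frailty models; the comparison inherits the proportional-hazards
  assumption.
* Landmark AUC discards early-censored subjects instead of reweighting.
* The registry ships only the cut-off systems printed in the source
  material; the several dozen other published systems must be supplied
  via the JSON config (`load_schemes()`).
* Jackknife ΔC uses O(n²) memory per model; intended for cohorts of
  hundreds to a few thousand subjects, not biobank scale.
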