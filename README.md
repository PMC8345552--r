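# lnstage

Comparing lymph node classification systems for overall-survival
discrimination in radically resected, non-metastatic colorectal cancer.

## The problem

The AJCC/UICC N category stages nodal disease by the raw count of
positive lymph nodes (N0: none, N1: 1–3, N2: ≥ 4). Because that count
depends on how thoroughly nodes were harvested, two ratio-based
alternatives are widely studied:

- **LNR** (lymph node ratio): `pLN / NELN`, positive over examined
  nodes;
- **LODDS** (log odds of positive lymph nodes):
  `ln((pLN + 0.5) / (NELN − pLN + 0.5))`, the empirical-logistic
  transform, which stays informative even when LNR saturates at 0 or 1.

Many cut-off systems have been published for both. `lnstage` implements
the machinery needed to compare such interval-based classifications
head-to-head against the N category on one cohort:

- covariate-adjusted Cox proportional-hazards models (age ≥ 70, sex,
  tumour size ≥ median, grade G3+G4, T3+T4, rectal location), fitted via
  the `survival` package behind a matrix interface;
- **Harrell's C** on each model's linear predictor, with a leave-one-out
  jackknife CI;
- **ΔC** between each scheme's model and the N-category model, with the
  jackknife variance of the paired difference
  (`var = ((n−1)/n) Σᵢ (d⁽⁻ⁱ⁾ − d̄)²`), normal 95% CI and p-value;
- **Benjamini–Hochberg FDR** over the scheme family within each
  subgroup;
- Kaplan–Meier / log-rank exports, landmark ROC AUC at 1/3/5 years, and
  Spearman correlations between the nodal metrics;
- a **seeded synthetic cohort generator** calibrated to the published
  summary tables (n = 654; UICC I/II/III = 171/232/251; NELN median 17,
  range 2–68; ≈ 252 deaths under 150-month follow-up), since the
  original patient data are not public;
- a registry of the seven published LNR/LODDS cut-off systems reported
  as superior in stage III disease, plus a cohort-quantile LODDS scheme
  and a JSON config format for user-defined schemes.

Intended users: clinical epidemiologists and biostatisticians evaluating
nodal staging proposals, and methodologists who need a tested reference
implementation of the paired jackknife C-statistic comparison.

## Worked example

```r
library(lnstage)

cohort <- simulate_cohort(sim_config(seed = 1))   # 654 subjects, 259 deaths
metrics <- add_nodal_metrics(cohort)
as.data.frame(metrics)[c(2, 1), c("id","pln","neln","lnr","lodds","n_cat","n_subcat","stage")]
#>     id pln neln lnr lodds n_cat n_subcat    stage
#>  P0002   2   10 0.2 -1.22    N1      N1b UICC_III
#>  P0001   0   16 0.0 -3.50    N0     none   UICC_I

res <- run_full_analysis(cohort, subgroups = "uicc")
subset(res$comparison, subgroup == "uicc: UICC III",
       c(scheme, c_index, delta_c, p, p_fdr))
#>                scheme c_index delta_c       p   p_fdr
#>            N category   0.714 0.00000      NA      NA
#>               LNR Lee   0.747 0.03239 0.00329 0.00659
#>    LNR Fortea-Sanchis   0.740 0.02565 0.04222 0.05629
#>  LODDS Fortea-Sanchis   0.740 0.02516 0.01688 0.02701
#>              LODDS He   0.754 0.03993 0.00179 0.00501
#>          LODDS Calero   0.731 0.01626 0.14224 0.16256
#>         LODDS Bagante   0.752 0.03773 0.00188 0.00501
#>        LODDS Jian-Hui   0.758 0.04393 0.00097 0.00501
#>        LODDS quantile   0.721 0.00667 0.59166 0.59166
```

Reading the table: each row is one classification system added to the
adjusted base model in the stage III subgroup of this synthetic cohort.
`c_index` is Harrell's C of that model, `delta_c` its jackknife-paired
difference against the N-category model, and `p_fdr` the BH-adjusted
p-value within the 8-scheme family. Because the default generator gives
the hazard a log-linear LODDS term, LODDS-based schemes genuinely carry
information beyond N here, and the machinery finds positive, significant
ΔC for several of them — the qualitative pattern the method is designed
to detect. Class-wise hazard ratios sit in `res$class_hr`:

```r
subset(res$class_hr, scheme == "LODDS Jian-Hui" & subgroup == "uicc: UICC III")
#>        subgroup         scheme       class   hr ci_low ci_high        p
#>  uicc: UICC III LODDS Jian-Hui      <=-1.5 1.00     NA      NA       NA
#>  uicc: UICC III LODDS Jian-Hui >-1.5; <=-1 2.14   1.24    3.69 6.42e-03
#>  uicc: UICC III LODDS Jian-Hui    >-1; <=0 1.96   1.25    3.07 3.15e-03
#>  uicc: UICC III LODDS Jian-Hui          >0 6.24   3.85   10.09 9.45e-14
```

Kaplan–Meier coordinates for plotting, grouped by a scheme or by the
stage III low/high-risk rule (high: T4 or N2):

```r
km <- export_km(subset_stage3, "risk")   # $curves, $logrank
```

## Acceptance script

`scripts/acceptance.R` exercises the full pipeline end to end: it
simulates the default synthetic cohort from `--seed`, runs the complete
scheme comparison (whole cohort and UICC subgroups), and writes the
target report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/lymph-node-classification.Rmd`) covers
the model and its assumptions, the jackknife inference, what the
synthetic generator does and does not emulate, numerical conventions
(tie handling, interval closures, repaired printed cut-offs), and known
limitations.
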