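# cescore

Centromere/kinetochore expression scoring for tumour cohorts.

## What problem this solves, and for whom

Overexpression of centromere and kinetochore (CEN/KT) genes — CENP-A, its
assembly machinery (HJURP, MIS18 complex), CCAN and KMN network components —
drives chromosomal instability in tumours. An additive expression signature
over these genes behaves both as a **prognostic** biomarker (high scores
predict poor survival in untreated patients) and a **predictive** one
(high-score tumours are preferentially sensitized to genotoxic therapy:
Topo I inhibitors, platinum chemotherapy, radiotherapy). This package is for
computational biologists who want to derive, compute and evaluate such a
signature on expression cohorts with clinical annotation — or to validate
the full methodology on synthetic cohorts with known ground truth.

## The score

For a gene panel *P* and sample *j* with log2 expression *x<sub>gj</sub>*:

&nbsp;&nbsp;&nbsp;&nbsp;CES<sub>j</sub> = Σ<sub>g∈P</sub> x<sub>gj</sub>

an unweighted sum of log2 expression (linear input is converted with
log2(x+1)). Panels shipped: `cenkt31` (31 CEN/KT structural/assembly genes),
`ces14` (14-gene core panel), `ces9` (core panel minus the five genes absent
from the HG-U133A platform). Around the score the package provides:

* tumour/normal differential-expression screening (Welch or moderated
  d-statistic), a cross-dataset ≥2-fold / FDR ≤ 0.05 / ≥50%-prevalence
  filter, permutation confirmation, and panel derivation from prognostic
  evidence sets;
* tertile/quartile/cutpoint stratification (quantile or equal-width range
  tertiles; minimal-p cutpoint scan with an explicit uncorrected-p flag);
* association analyses: Spearman + joint FDR (genomic instability),
  rank tests and contingency enrichment (clinical factors), correlation
  network edge lists (R ≥ 0.4), and CES-vs-IC50 drug sensitivity with
  Qn-based robust outlier exclusion;
* Kaplan–Meier / log-rank / multivariate Cox survival analysis (Efron
  ties), five-year survival chi-square, and treatment-stratified hazard
  (forest) tables with an n ≥ 30 subcohort floor;
* a deterministic synthetic-cohort generator (expression, survival with a
  treatment×stratum interaction, instability with a tunable Spearman
  target, drug response with injected outliers) for validation;
* a pipeline driver (`run_pipeline()`) and CLI (`inst/cli/cescore.R`).

## Worked example

Simulate one tumour cohort, score it with the core panel, stratify, and ask
whether adjuvant treatment helps specifically in the high-CES stratum:

```r
library(cescore)

cfg     <- sim_config(n_tumour = 120, seed = 42)   # planted world
sim     <- simulate_expression_datasets(cfg)
tumours <- subset_samples(sim$datasets$D1,
                          sim$datasets$D1$sample_roles == "tumour")
ces     <- compute_ces(tumours, load_gene_panel("ces14"))
strata  <- stratify(ces, "quantile_tertile")
cohort  <- simulate_cohort(cfg, ces$scores)

logrank_test(data.frame(time = cohort$time, event = cohort$event,
                        group = as.character(strata$strata[cohort$sample_id])))
fit <- cox_fit(cohort, data.frame(ces_z = as.vector(scale(cohort$ces)),
                                  grade = factor(cohort$grade)))
ft  <- stratified_treatment_analysis(cohort,
                                     stratify(ces, "top_tertile_vs_rest"))
```

Output (printed by the code above):

```
log-rank chi-square = 16.41 (df = 2), p = 0.000274

    term    coef    hr ci_low ci_high    se        p
1  ces_z  0.6400 1.896  1.312    2.74 0.188 0.000671
2 grade2 -0.1134 0.893  0.427    1.87 0.376 0.763140
3 grade3 -0.0754 0.927  0.376    2.29 0.461 0.869913

                      analysis    hr ci_low ci_high   p_wald  n events
1        treatment_within_high 0.370  0.143   0.957 0.040311 40     18
2         treatment_within_low 1.617  0.720   3.635 0.244634 80     26
3   high_vs_low_within_treated 0.999  0.411   2.428 0.998939 69     24
4 high_vs_low_within_untreated 5.400  2.006  14.534 0.000843 51     20
```

Reading it: CES tertiles separate survival (log-rank p ≈ 3×10⁻⁴); the Cox
hazard ratio per standardized CES unit is 1.90 (planted truth e^0.7 ≈ 2.01)
and survives grade adjustment; treatment benefits the high-CES stratum
(HR 0.37, p = 0.04) but not the low stratum (CI spans 1), and high CES is
hazardous only among untreated patients — the prognostic-but-predictive
pattern the signature is designed to detect.

## Documentation

The methods vignette (`vignettes/ces-methods.Rmd`) describes the model and
its assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
conventions (tie handling, boundary assignment, the log-scale Qn exclusion
rule, the add-one permutation estimator), and known limitations.
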