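---
title: "Centromere/kinetochore expression scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centromere/kinetochore expression scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cescore)
```

## The problem

Misregulation of centromere and kinetochore (CEN/KT) genes — CENP-A and its
assembly factors (HJURP, the MIS18 complex), the CCAN inner-kinetochore
network, and the KMN outer-kinetochore network — causes chromosome
missegregation and chromosomal instability (CIN). Tumours that overexpress
these genes tend to carry more genomic damage, behave more aggressively, and,
because their instability is already near a tolerable ceiling, respond better
to genotoxic therapy (Topo I inhibitors, platinum chemotherapy,
radiotherapy). `cescore` implements an additive expression signature that
quantifies this misregulation per sample, together with the screening,
stratification, association and survival machinery needed to evaluate it as
a prognostic and predictive biomarker.

## The score

For a gene panel $P$ and a sample $j$ with log2 expression $x_{gj}$,

$$\mathrm{CES}_j = \sum_{g \in P} x_{gj}.$$

The score is deliberately an unweighted sum: no z-scoring, gene weighting or
enrichment variant. Linear-scale input is transformed as $\log_2(x + 1)$
first; the pseudocount of 1 keeps normalized counts of zero finite and is
negligible at typical expression magnitudes. Consequences that the tests
verify exactly: adding $c$ to one panel gene's log2 values shifts every score
by $c$; panel order is irrelevant; raising any panel gene's expression never
lowers a score.

Three panels ship with the package: `cenkt31` (31 structural and assembly
CEN/KT genes), `ces14` (the 14-gene core panel of consistently
tumour-overexpressed, prognostically supported genes) and `ces9` (the core
panel minus the five genes without probes on the Affymetrix HG-U133A
platform — CENPW, CENPL, CENPK, SPC24, NUF2 — for meta-analyses restricted
to that platform). Twelve `ces14` members are fixed by the primary
description; the full published listing resides in supplementary material
that is not distributed here, so the two remaining members (CENPU, ZWINT)
are documented stand-ins chosen to satisfy the published structural
constraints (CCAN/KMN members, no MIS12 complex). Panel files are data under
`inst/extdata/panels/`, not code; every size/subset relation used by the
tests holds for the shipped files.

If panel genes are missing from a matrix the default is an error; the
explicit `allow_missing` override rescales the score by
`panel_size / n_available` so that scores stay on the full-panel scale, and
flags the result. This mirrors the explicit 9-gene fallback rather than
silent gene dropping.

## Panel derivation

The screening pipeline reproduces the published selection logic:

1. **Per-dataset differential expression.** Default engine: Welch's t-test
   on log2 values, with the fold change defined as the difference of log2
   means (log2 ratio of geometric means). Benjamini–Hochberg adjustment is
   applied within each dataset. A `moderated` engine (SAM-style d-statistic
   with offset `s0` = median per-gene standard error and a pooled
   label-permutation null) is provided for sensitivity analysis; the
   original add-on's internal settings are unreported, so the Welch engine
   is the default and no equivalence is claimed.
2. **Cross-dataset prevalence filter.** A gene passes a dataset when
   q ≤ 0.05, fold change ≥ 2 and direction is up; it is retained when it
   passes in at least `ceiling(prevalence × n_datasets)` datasets. "At
   least 50%" is boundary-ambiguous for odd dataset counts; the ceiling
   convention (strict majority when n is odd) is used and documented.
3. **Permutation confirmation.** Per gene, sample labels are permuted B
   times and `p = (1 + #{permuted fc ≥ observed}) / (B + 1)` — the add-one
   estimator, which cannot return zero and is slightly conservative.
4. **Evidence intersection.** The final panel is the set of consistently
   upregulated genes supported by at least one prognostic evidence source;
   a single source suffices because platform-limited sources can lack
   probes for genes that others cover. Provenance per member is recorded.

## Stratification

Two tertile conventions coexist because both appear in practice:
`quantile_tertile` (empirical 1/3 and 2/3 quantiles; the default) and
`range_tertile` (equal-width thirds of the observed score range). Every
output records its mode. Bins are closed on the right: a score exactly at a
boundary goes to the lower stratum — deterministic and documented.
`top_tertile_vs_rest` is the binary split used for treatment analyses, and
`quartile` the four-bin mode used for cell lines.

`best_cutpoint()` scans the unique observed scores clipped to the 10th–90th
percentiles and returns the cutoff minimizing the two-group log-rank p. The
returned p is a minimal p over the scan and is **not** corrected for the
selection; the result object says so (`minimal_p = TRUE`) and the test suite
demonstrates the type-I inflation under an exchangeable null. Cohorts below
30 subjects are refused, matching the meta-analysis floor.

## Associations

* **Spearman + FDR**: average-rank ties, two-tailed p via the t
  approximation; BH adjustment is computed jointly across all rows of a
  table (one FDR family per table, matching a single-FDR-column layout).
  Degenerate (constant) rows are excluded from the family with a note.
* **Rank tests**: Wilcoxon rank-sum (plain normal approximation with
  tie-corrected variance, no continuity correction) for two groups,
  Kruskal–Wallis otherwise.
* **Enrichment**: chi-square without continuity correction by default;
  Fisher's exact test when the table is 2×2 and any expected count is
  below 5. The policy used is recorded; the underlying study used both tests
  without stating a rule, so this is a convention, not a claim.
* **Co-expression network**: Pearson correlation across samples, undirected
  edges for r ≥ 0.4 (threshold configurable); only the edge list and degree
  table are emitted — no layout.

### Robust outlier exclusion (Qn)

Extreme IC50s are excluded by a one-sided rule: drop values above
`median + 3 × Qn`. The Qn estimator — the k-th order statistic of all
pairwise absolute differences with `h = floor(n/2) + 1`, `k = choose(h, 2)`,
scaled by the Gaussian consistency constant 2.2219 and a finite-sample
factor — is the canonical location-free scale estimate that is more
efficient than the MAD under normality. The raw kernel is exposed alongside
the scaled estimate so the constant choice can never silently change an
exclusion. Two numerical paths give identical results: full enumeration for
n ≤ 500, and exact selection (binary search on the value with two-pointer
pair counting) above that, avoiding O(n²) memory at n = 10,000.

The rule is applied to **log** IC50. IC50s are log-normal to first order;
on the linear scale a `median + 3·Qn` cutoff would flag a large fraction of
perfectly clean lognormal data (≈12% at the generator's default noise),
whereas on the log scale the false-flag probability per clean value is the
Gaussian ≈0.0013. The exclusion is one-sided (above the median only), as
worded in the source methods; a two-sided variant exists but is off by
default.

## Survival analysis

Estimation is delegated to the CRAN `survival` package behind this package's
interfaces: product-limit curves (`survfit`), k-group log-rank (`survdiff`)
and Cox partial likelihood with **Efron** tie handling (`coxph`; more
accurate than Breslow under the heavy ties of discretized follow-up, and
recorded in the output). The test suite checks each operation against
independent brute-force oracles: a hand product-limit computation, a
hypergeometric observed-vs-expected accumulation, and a 1-D partial
likelihood grid search. Wald confidence intervals and p-values are reported;
the tie-handling and CI conventions are this package's documented choices,
not claims about the original analysis.

Five-year survival comparisons classify each subject at the horizon: event
before it = not surviving, event-free follow-up past it = surviving, and
subjects censored before it are excluded with their count always reported
(the original work reports only percentages, so the exclusion convention is
made explicit here).

`stratified_treatment_analysis()` produces the four-row forest table behind
a prognostic-vs-predictive evaluation — treatment effect within the high and
low CES strata, and high-vs-low effect within the treated and untreated
arms — each with Cox HR/CI/p and a log-rank p, dropping rows whose subcohort
falls below the n ≥ 30 floor.

Endpoint labels (OS, DFS, RFS, DMFS, FP, PFS, relapse) are metadata: the
estimators are endpoint-agnostic, but mixing endpoints in one test is an
error.

## The synthetic cohort

No external cohort is downloadable at test time, so a generator with known
ground truth stands in for the GEO/TCGA/CCLE inputs. It emulates:

* **Expression**: independent Normal noise per gene on the log2 scale
  (log-normal on the linear scale), matching microarray log-intensity
  conventions and making planted fold changes exact in expectation. Default
  stated world: 4 datasets × (30 normal + 30 tumour), 200 background genes,
  panel genes planted at log2FC 1.5 with SD 0.5. The 1.5 plant is the
  generator's stated default; planting exactly at the fold-change boundary
  (1.0) would make per-dataset pass probability ½ by construction.
* **Survival**: exponential baseline (constant hazard 0.1 per time unit) —
  the simplest process satisfying proportional hazards, so Cox recovery is
  well-posed — with uniform censoring on (0, 10]. Treatment enters only
  through an interaction with the high stratum (`treat_beta`, default −0.9),
  mirroring the finding that therapy benefits high-CES patients
  specifically; the main treatment effect defaults to zero but is
  configurable.
* **Instability**: a Gaussian-copula monotone link. The CES normal scores
  are mixed with independent noise at Pearson correlation
  `2·sin(π·r_s/6)`, the exact inversion of the bivariate-normal
  Spearman/Pearson relation, so `assoc_slope` *is* the target Spearman
  correlation; CNA latents are squashed through a logistic into [0, 1] and
  mutation latents exponentiated — both monotone, preserving the target.
* **Drug response**: a latent per-line activity loaded on every panel gene,
  log IC50 = 2 − `ic50_slope`·z(CES) + Normal noise (SD 1), and
  `n_outliers` lines replaced by 100× the bulk median IC50 with their ids
  recorded.
* **Covariates**: grade/ER/histology drawn from latent-logistic links with
  slope 0.8 per standardized CES unit. The source tables give only marginal
  percentages, never effect sizes, so these defaults are chosen once for
  testability, not realism.

One global seed expands into four fixed substreams (expression / cohort /
instability / drug), so identical configurations are byte-identical and each
generator can be rerun independently.

What a green test does **not** establish: the generator has no batch
effects, probe saturation, platform differences, tumour purity variation or
realistic marginal distributions, so passing recovery tests demonstrates
correctness of the estimators on the assumed model, not fidelity to any real
cohort.

## Numerical choices and degenerate inputs

* All-equal scores refuse to stratify (explicit degenerate error, never a
  silent single group); quantile modes need at least k distinct values.
* Constant genes: excluded from networks with a note; permutation test
  warns and returns p = 1; constant covariates refuse a Cox fit.
* Probe collapsing defaults to the mean of log2 values per gene (symmetric,
  variance-reducing); `max_mean_probe` supports jetset-style workflows. The
  aggregation rule used originally is unstated, so the default is a
  documented convention. Genes with no mapped probe are reported, never
  silently dropped.
* Gene identifiers are opaque, case-sensitive strings; alias resolution is
  the caller's concern (e.g. via a probe map), not hard-coded.
* Pipeline logs carry no timestamps, so reruns under one seed are
  byte-identical — determinism is a tested property, not an aspiration.

## Known limitations

* No CEL-file processing, normalization or batch correction; inputs are
  assumed normalized.
* No time-varying covariates, competing risks or formal proportionality
  diagnostics; the Cox model is used exactly as in the source analyses.
* No dose–response fitting; IC50s are taken as given.
* The minimal-p cutpoint scan is exploratory by construction; its p-value
  must not be reported as confirmatory.
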