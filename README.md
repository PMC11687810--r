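# plasmiR

Circulating microRNAs measured by RT-qPCR are candidate diagnostic and
prognostic markers in oncology — including canine appendicular osteosarcoma,
where plasma miR-214-3p levels track both diagnosis and survival. Analyzing
such panels properly takes more than a t-test: plates must be calibrated
against each other, undetected wells handled conservatively, hemolysis
(erythrocyte miRNA contamination, indexed by 414 nm absorbance) screened per
miRNA, endogenous controls chosen by a defensible stability criterion,
expression normalized by the comparative-Ct method, and the survival
questions answered with optimal-cutpoint dichotomization, Cox regression and
pruned decision trees. plasmiR packages that entire chain for
biostatisticians and veterinary/clinical researchers running plasma or serum
miRNA panels, together with a synthetic-cohort generator that emulates the
statistical structure of a multi-cohort case/control study so every stage
can be validated against planted ground truth.

## What it computes

* **Plate QC** — inter-plate calibration by the no-template calibrator rule
  (offset `o_p = mean(C_p) − grand mean`, subtracted from every well), a
  35.00-cycle detection ceiling, spike-in ±2 SD filters, and sample/assay
  detection filters with machine-readable exclusion reasons.
* **Hemolysis screen** — sample admission and 3-class labeling from 414/375
  nm absorbance; per-miRNA verdicts from the R² of Ct on A414 plus a
  hemolyzed-vs-not rank-sum test (affected: R² > 0.3 and p < 0.01;
  unaffected: R² < 0.2 and p > 0.05; otherwise indeterminate).
* **Controls & normalization** — model-based (NormFinder-style) stability
  `ρ_i = mean_g(|d*_ig| + sqrt(w_ig + σ²_ig/n_g))` over a two-way
  gene × sample model; best-pair-plus-third selection with a
  pairwise-variation test for a fourth control; comparative-Ct
  normalization `ΔCt* = geomean(control Ct) − Ct` (larger = more abundant)
  and fold differences `FD = FC if FC ≥ 1 else −1/FC` with
  `FC = 2^(ΔCt*_case − median ΔCt*_control)`.
* **Differential expression** — Shapiro–Wilk gate (recorded), two-sided
  Wilcoxon rank-sum per miRNA and cohort, Benjamini–Hochberg FDR within
  each cohort comparison.
* **Survival** — Kaplan–Meier, log-rank with pairwise Bonferroni,
  maximally selected cutpoints (minprop 0.2), fixed 183/365/730-day
  horizons, and univariate Cox (Newton/Efron) with one-vs-rest expansion
  of categorical covariates.
* **Trees** — Gini classification trees (diagnosis) and exponential-
  deviance survival trees (prognosis) grown unrestricted and pruned by
  10-fold cross-validated cost-complexity; accuracy/precision/recall/AUC
  on a held-out cohort; tree-group survival comparison with rate-ratio or
  Cox hazard ratios.
* **Pipeline** — `runPipeline()` orchestrates all stages into a run
  directory of CSV/JSON artifacts, fully reproducible from one seed; a
  thin CLI lives in `inst/scripts/plasmir.R`.

## Worked example

```r
library(plasmiR)

cohort <- generateCohort(cohortConfig(seed = 11))   # 82 samples, 56 assays
qc     <- plateQc(cohort$plates, cohort$samples)
qc$report
#> QcReport
#>   plate offsets (Ct): plate1=-0.405, plate2=+0.158, plate3=+0.301, plate4=-0.054
#>   excluded samples: 0  excluded assays: 6

hs   <- hemolysisScreen(qc$matrix, qc$samples)
ctrl <- selectControls(qc$matrix, qc$samples$group, hs$verdicts,
                       whitelist = c("hsa-let-7c-5p", "cfa-miR-140"))
ctrl
#> ControlSet: cfa-miR-23b, rno-miR-223-3p, hsa-miR-27b-3p
#>   pairwise variation V3 = 0.1809 (three controls sufficient)

norm <- normalizeCt(qc$matrix, ctrl)
head(deTable(norm, qc$samples, "cohort1"), 3)
#>     assay_id  cohort    raw_p    fdr_p median_fd normal direction
#> 1 miR-214-3p cohort1 3.98e-08 1.87e-06      8.90  FALSE        up
#> 2 miR-sim-11 cohort1 2.39e-02 5.61e-01     -1.36   TRUE        ns
#> 3 miR-sim-22 cohort1 7.15e-02 7.56e-01     -1.51   TRUE        ns

ci <- which(qc$samples$group == "case")
cp <- maxSelectedCutpoint(exprValues(norm)[ci, "miR-214-3p"],
                          qc$samples$os_time[ci], qc$samples$os_event[ci])
logrankTest(qc$samples$os_time[ci], qc$samples$os_event[ci], cp$groups)$chi2
#> cutpoint -0.11; log-rank chi2 18.5 (p = 1.7e-05); HR high vs low 4.22 (2.10-8.45)
```

The plate offsets recover the planted calibration drift; the six planted
near-undetectable assays are the six exclusions; the planted marker tops
the differential-expression table (median fold-difference 8.9, i.e. about
2^2.4-fold up in this cohort draw, FDR 2e-6) and its high-expression group
has a hazard ratio of 4.2 for overall survival — the structure the
generator planted.

For a full run writing every stage artifact to disk:

```r
runPipeline(pipelineConfig(outDir = "run1", seed = 42))
```

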