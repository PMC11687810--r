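---
title: "Methods: plasma miRNA RT-qPCR biomarker analysis with plasmiR"
author: "plasmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma miRNA RT-qPCR biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plasmiR implements the full analysis chain used in circulating-miRNA
RT-qPCR biomarker studies of the kind run on custom PCR arrays against
plasma from case and control cohorts: plate calibration and quality
filtering of Ct values, spectrophotometric hemolysis screening,
endogenous-control selection by a model-based stability criterion,
comparative-Ct normalization, rank-based differential expression, optimal
cutpoint survival analysis, and CART-style diagnostic and prognostic trees.
This vignette records the statistical models behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
cohorts used by the test suite do and do not establish about real data.

## 1. Plate calibration and quality filters

RT-qPCR arrays drift plate to plate. Each array carries no-template
replicates of a synthetic inter-plate calibrator; the per-plate offset is

$$o_p = \bar{C}_p - \frac{1}{P}\sum_{q} \bar{C}_q,$$

the plate's mean calibrator Ct minus the grand mean of the per-plate means,
and every well's Ct on plate $p$ is reduced by $o_p$. After correction all
per-plate calibrator means coincide exactly. Corrected values feed a
conservative detection ceiling (default **35.00 cycles**): undetected
wells, values above the ceiling, and wells whose amplification curve failed
review are all set to exactly 35.00 and flagged. "Detected" thereafter
means strictly below the ceiling.

Three filters follow, all with statistics computed once on the complete
input before any exclusion, so they are single-pass and order independent:

* **Spike-in filter** — each sample's isolation and reverse-transcription
  spike-in Ct must lie within mean ± 2 SD of that spike-in across all
  samples. Zero SD or a single sample passes everything (no evidence of
  deviation); missing spike-ins fail with reason `missing_spike`.
* **Sample detection filter** — a sample's detection count must be at
  least the mean count minus 2 SD (one-sided). Detection *count* is used
  as the notion of overall expression, mirroring the assay-level filter;
  mean Ct would be a defensible alternative but couples the filter to
  abundance.
* **Assay prevalence filter** — an assay is dropped when the number of
  samples expressing it falls strictly below the mean prevalence minus
  2 SD. Note the arithmetic of this rule: with $f$ the fraction of
  near-undetectable assays, the threshold is positive only for
  $f \lesssim 0.2$, so the filter isolates a small tail of dead assays
  rather than trimming a continuum.

Every exclusion carries exactly one machine-readable primary reason.

## 2. Hemolysis screening

Erythrocytes carry miRNAs; hemolysis therefore distorts plasma profiles.
Hemoglobin absorbs at 414 nm and lipid content inflates that reading, which
absorbance at 375 nm corrects. The sample rules (absorbance units):

* admission: $A_{414} < 1.5$ **or** $A_{414}/A_{375} < 1.4$ (lipemic
  rescue);
* classes: $A_{414} \le 0.2$ non-hemolyzed; $> 0.2$ with ratio $\ge 1.4$
  hemolyzed; $> 0.2$ with ratio $< 1.4$ lipemic non-hemolyzed. Lipemic
  samples join the non-hemolyzed group in the rank test but are excluded
  from the regression, since their 414 nm reading does not measure
  hemoglobin.

Per miRNA, two lines of evidence: the OLS $R^2$ of Ct on $A_{414}$ over the
regression set, and a two-sided rank-sum p comparing hemolyzed against
non-hemolyzed samples. Verdicts: **affected** when $R^2 > 0.3$ and
$p < 0.01$; **unaffected** when $R^2 < 0.2$ and $p > 0.05$; otherwise
**indeterminate**. Boundary values are indeterminate — the inequalities are
strict. The rank-sum test is two-sided (sidedness is a convention here;
coupling is directional but contamination is what matters), exact when both
groups have at most 8 samples and tie-free, else normal approximation with
tie correction and no continuity correction. Verdicts are advisory:
affected assays are barred from control candidacy and from prognostic
models; indeterminate assays are barred from candidacy unless explicitly
whitelisted; unaffected assays are unrestricted. Cases and controls are
pooled in the regression (hemolysis is a property of the specimen, not the
disease).

## 3. Endogenous-control selection and normalization

Stability is estimated with a model-based variance decomposition on the Ct
scale (already log-scale). For candidate $i$, group $g$, sample $j$:

$$y_{igj} = \alpha_i + d_{ig} + b_{gj} + \varepsilon_{igj},\qquad
\varepsilon_{igj} \sim (0, \sigma^2_{ig}),$$

with sample effects $b_{gj}$ removed by centering each sample over the
candidate set, per-candidate group biases $\hat d_{ig}$ constrained to sum
to zero over groups, residual variances debiased for the centering
($\hat\sigma^2_{ig} = \max\{0, (s^2_{ig} - \bar s^2_g/(k-1))\,k/(k-2)\}$
for $k \ge 3$ candidates), and the biases shrunk toward zero by an
empirical-Bayes factor $\hat\gamma^2/(\hat\gamma^2 + v_{ig})$ where
$v_{ig}$ is the sampling variance of $\hat d_{ig}$ and $\hat\gamma^2$ a
method-of-moments estimate of the between-candidate bias variance. The
stability value (lower = more stable) combines bias magnitude and variance:

$$\rho_i = \frac{1}{G}\sum_g\Big(|d^*_{ig}| +
\sqrt{w_{ig} + \hat\sigma^2_{ig}/n_g}\Big),$$

and a candidate set $S$ scores
$\rho_S = \frac1G\sum_g\big(\mathrm{mean}_{i\in S}|d^*_{ig}| +
\sqrt{\textstyle\sum_{i\in S}(w_{ig}+\hat\sigma^2_{ig}/n_g)}/|S|\big)$.
Averaging the absolute shrunken biases (rather than the absolute average)
prevents two oppositely biased candidates from masquerading as a stable
pair by cancellation — with small candidate sets the zero-sum constraint on
$d$ makes that a real failure mode.

Selection: candidates must be expressed in every sample and carry no
adverse hemolysis verdict; the chosen set is the best pair plus the
candidate minimizing the trio's combined stability. A fourth control is
added only when it provides a *significant reduction in variability*,
operationalized as: the four-member combined stability improves on the
trio's, **and** the pairwise variation
$V_3 = \mathrm{SD}_s\big(NF_3(s) - NF_4(s)\big)$ between the three- and
four-control normalization factors exceeds 0.15 (the conventional cut-off);
a fourth that leaves the factor essentially unchanged is unnecessary. The
full decision — candidates, exclusions with reasons, ranked stabilities,
pair and trio search, $V_3$ — is recorded in a replayable audit.

Normalization is comparative-Ct in one pass over the combined sample set:

$$\Delta Ct^*(s, a) = \Big(\prod_{c \in \text{controls}} Ct(s,c)\Big)^{1/|C|}
 - Ct(s, a),$$

so **larger values mean more abundant miRNA**. The geometric average is
applied literally to Ct values (it is less outlier-sensitive); note that
this makes per-sample additive shifts cancel only to first order — for
control Cts in the low twenties the residual is below 0.01 cycles, and the
arithmetic mean (exactly shift-equivariant) differs from it by well under
0.05 cycles. Control assays remain in the normalized matrix but are
excluded from downstream testing and modeling (a control normalized against
a set including itself is a self-normalization artifact).

Fold changes per case sample are
$FC = 2^{\Delta Ct^*_{case} - \mathrm{median}(\Delta Ct^*_{control})}$, the
reported per-miRNA statistic is the median $FC$ over the cohort's cases,
and fold differences symmetrize it: $FD = FC$ if $FC \ge 1$, else $-1/FC$
(so $|FD| \ge 1$ and upregulation always reads as $FD > 1$). The two
textbook conventions for the sign of $\Delta\Delta Ct$ conflict; this
package fixes the orientation by the invariant *upregulated ⇒ FD > 1*.

## 4. Differential expression

Per retained miRNA and per case cohort against the single control group: a
Shapiro–Wilk gate per group is computed and recorded (normal only when
every group has $p > 0.05$; undefined for constant or tiny groups), but the
pipeline applies non-parametric tests throughout — the study-design choice
when a sizeable minority of miRNAs is non-normal, rather than per-miRNA
test switching. The test is the two-sided Wilcoxon rank-sum described
above; multiplicity is controlled by Benjamini–Hochberg within one
cohort-vs-control comparison (the panel is the family), significance at
adjusted $p < 0.05$. Direction calls combine the adjusted p with the median
fold difference.

## 5. Survival analysis

* **Kaplan–Meier**: product-limit estimator; the median is the smallest
  observed time where $S(t) \le 0.5$, undefined when never reached.
* **Log-rank**: the standard $\left(O-E\right)^2/V$ chi-square on one
  degree of freedom with the hypergeometric variance; pairwise comparisons
  over more than two groups multiply each raw p by the number of pairs
  (Bonferroni), capped at 1.
* **Fixed horizons** (183/365/730 days): administrative censoring at the
  horizon, which makes event status monotone across increasing horizons.
* **Maximally selected cutpoints**: candidate cutpoints are midpoints
  between consecutive distinct expression values whose split leaves at
  least a fraction `minprop` (default 0.2) of samples per side — side
  counts of at least the smallest integer $\ge$ `minprop`·n, so tied
  values are never split. The cutpoint maximizing the absolute
  standardized log-rank statistic is selected (ties toward the smaller
  cutpoint), "high" being the more-abundant side. No small-sample
  selection correction is applied and the downstream p is the ordinary
  log-rank on the categorized groups; such p-values are optimistic, a
  known property of optimally selected cutpoints that users should keep in
  mind (a Lausen–Schumacher-type correction is out of scope).
* **Univariate Cox regression**: partial likelihood maximized by damped
  Newton iterations (step halving on likelihood decrease) with Efron tie
  handling; Wald CIs from the observed information. Categorical covariates
  are expanded one-versus-rest, one fit per category, so a variable with
  $n$ categories yields $n$ hazard ratios; single-sample categories are
  inestimable, and monotone likelihoods (separation) are flagged with an
  unbounded CI rather than a spurious estimate.

## 6. Diagnostic and prognostic trees

Classification trees minimize Gini impurity; survival trees use the
exponential-model deviance
$D = 2\sum_i\big[\delta_i\log(\delta_i/(\hat\lambda t_i)) +
(\hat\lambda t_i - \delta_i)\big]$ with the node rate
$\hat\lambda = \sum\delta_i/\sum t_i$, splitting to maximize
$D_{parent} - (D_{left}+D_{right})$. Leaves of a survival tree report the
event-rate ratio against the root — the "hazard ratio" of the group — with
a Cox-on-leaf-indicator alternative available in the group comparison
(`hrMethod = "cox"`), since rate ratio and Cox coefficients are both
reasonable readings of a tree-group HR.

Growth defaults mirror the recursive-partitioning ecosystem's: minimum 20
samples to split, minimum leaf 7, initial complexity threshold 0.01 of the
root criterion, 10-fold cross-validation; all configurable. Pruning is
weakest-link cost-complexity on the misclassification count
(classification) or deviance (survival): the nested path of subtrees is
computed, each fold re-grows the tree and is pruned at the geometric means
of consecutive path alphas, and the returned subtree attains the minimum
cross-validated error with ties resolved toward the smaller tree. Held-out
survival deviance uses the training-fold leaf rates floored at half an
event over the training exposure, so a zero-event leaf cannot yield an
infinite deviance. The CV fold assignment is seeded and recorded in the
prune trace.

The diagnostic protocol trains on the first two case cohorts plus 80% of
controls and tests on the held-out cohort plus the remaining controls.
Metrics treat cases as the positive class; the AUC is the rank
(Mann–Whitney) statistic of the leaf class-probability scores with ties
mid-ranked. Prognostic trees pool all cases and consider only
hemolysis-unaffected markers; the multivariable variant adds clinical
covariates (age, weight, one-hot sex/location/ALP status) for the
clinically annotated cohorts. Missing predictor values route to the larger
child (no surrogate splits).

## 7. The synthetic cohort generator

`generateCohort()` is first-class, tested code that emulates the data
structure the pipeline assumes — it is how the package demonstrates
recovery of planted truths. The default configuration describes a
three-cohort case/control study: 35 + 13 + 13 cases against 21 controls,
56 assays on four plates with offsets between −0.4 and +0.3 cycles, six
near-undetectable assays, erythrocyte-derived assays coupled to hemolysis,
and one planted marker (a miR-214-3p analogue) upregulated by 2.37 cycles
in cases (≈ 5.2-fold) whose high-expressing tumours carry a log 2.9 excess
hazard.

Model choices, each fixed once at design time:

* **Noise**: per-well Gaussian Ct noise, SD 0.8 — the standard qPCR
  assumption; designated endogenous-control candidates use SD 0.2 and the
  whitelist (mildly hemolysis-coupled) candidates SD 0.6, giving the
  stability analysis a planted dominant trio, a realistic contrast for
  well-chosen control assays.
* **Per-sample efficiency**: a global Ct shift per sample (SD 0.3),
  removed by normalization.
* **Hemolysis**: latent 414 nm absorbance from a mixture (70% clean below
  0.2, 20% hemolyzed up to 1.2, 10% lipemic with ratio below 1.4);
  375 nm = 414 nm over a ratio near 1.6. Coupling slopes near −3 Ct per
  absorbance unit reproduce the moderate linear association
  ($R^2 \approx 0.4$) typical of hemolysis-affected plasma miRNAs.
* **Survival**: the hazard acts on a planted *binary* high/low expressor
  label per linked assay (Bernoulli ½ within cases), with expression
  shifted by ± half the expression heterogeneity (default 2.4 cycles,
  about five-fold — within the 2–9-fold range typical of dichotomized
  plasma markers) around the case shift. A binary latent is the one
  mechanism under which the event-rate ratio between planted groups
  converges exactly to the exponential of the link coefficient, which is
  what the cutpoint and tree analyses estimate. Times are exponential
  proportional hazards (baseline median 400 days overall survival, 330
  disease-free) with independent exponential censoring at an expected 15%.
  The two endpoints are drawn independently given the same latent groups —
  a simplification; real OS and DFI are positively coupled beyond their
  shared risk factors.
* **Spike-ins**: technical variation truncated at ±1 SD of its Gaussian
  (bounded pipetting variation); the ±2 SD filter then catches planted
  gross failures rather than routinely clipping the tails of a clean
  study.
* **Undetected wells** beyond 40 cycles are reported as missing Ct, so the
  ceiling rule is exercised on real missingness.

What passing tests on these cohorts do *not* show: robustness to
non-Gaussian Ct noise, amplification-efficiency differences between
assays, plate-by-assay interactions, non-exponential baseline hazards,
informative censoring, or correlated miRNA co-regulation. The generator
plants independent assays; real panels are correlated, which mainly makes
multiplicity control conservative and tree selection less stable than the
synthetic results suggest.

## 8. Numerical conventions and degenerate inputs

* Filter SD of zero, or a single sample/assay, passes everything.
* Fully tied rank-sum inputs give p = 1; constant groups make the
  normality gate undefined (recorded, not an error).
* A constant expression vector has no admissible cutpoint (error), as does
  a sample set smaller than 1/minprop.
* Cox on a constant covariate is an error; separation is flagged;
  single-sample categories are inestimable.
* Tree routing of unseen/missing values follows the larger child with a
  warning; pure nodes and nodes under the minimum split size become
  leaves.
* All randomness (fold assignment, train/test splits, the generator)
  derives from named seeds; identical configuration and seed reproduce
  byte-identical pipeline artifacts.

Problem sizes used by the test suite — study-shaped cohorts (82 samples,
56 assays) for recovery and calibration runs, with 100-seed recovery
sweeps, 200 null differential-expression runs and 200 random instances for
the cutpoint oracle — were chosen so the whole suite documents the
method's operating characteristics at the study's own scale.

## 9. Known limitations

* Cutpoint p-values are not corrected for maximal selection (reported as
  the field convention does, optimism acknowledged above).
* The survival-tree "HR" is an exponential rate ratio; under strongly
  non-exponential within-group hazards it is a coarse summary (the Cox
  alternative is provided).
* With ~40+ candidate markers and ~50 events, minimum-CV-error pruning of
  survival trees is conservative: moderate planted signals (hazard ratio
  near 3) are frequently pruned to the root — a property shared by the
  reference recursive-partitioning implementation and visible in the
  package's own recovery sweeps, not an artifact of this implementation.
* The amplification-curve review flag is a hook; automated curve QC from
  fluorescence data is out of scope, as are melt-curve analysis and
  miRNA-ratio hemolysis indicators.
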