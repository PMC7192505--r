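---
title: "Scanning the model space of translational drug-response pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning the model space of translational drug-response pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmscan)
```

## The problem

Translational drug-response models are trained on cell-line screens —
genome-wide expression profiles paired with a continuous drug-sensitivity
readout, ln(IC50), where lower values mean a more sensitive line — and
then applied to patients, whose response is a binary responder /
non-responder label derived from clinical categories or a median split of
progression-free survival. Between the two sides sits a severe domain
gap: different measurement platforms, different normalizations and
different biology produce systematically shifted expression
distributions, so some form of train/test homogenization is part of
every serious pipeline.

A pipeline here is one choice at each of five stages:

1. **Cell-response transform** (5 options): identity, natural log with a
   min-plus-one offset, a Box-Cox power transform, or binarization at the
   median or by two-cluster k-means.
2. **Homogenization** (7): none, pooled quantile normalization, two-batch
   empirical-Bayes adjustment (ComBat), gene-wise linear batch-term
   removal, two variants of removing unwanted variation estimated from
   housekeeping negative controls (SVD-based, and PCA + regression), and
   a per-sample cumulative-proportion transform.
3. **Feature filter** (4): all shared genes, a landmark-gene list, the
   top 80% by training variance, or the 80% with lowest t-test p-values
   between extreme responder groups.
4. **Feature preprocessing** (4): none, sample-wise or gene-wise
   z-scoring, or projection on the first 10 training principal
   components.
5. **Black box** (7): ordinary least squares (minimum-norm when features
   outnumber samples), lasso, elastic net (mixing 0.5) and ridge with
   10-fold cross-validated regularization, random forests with 500
   trees, a fast forest with 10,000 trees, and a radial-kernel SVM, all
   fitted as regressions (binary targets are coded 0/1 so every
   algorithm yields a continuous score for ROC analysis).

The full Cartesian product is `r 5 * 7 * 4 * 4 * 7` pipelines.
`enumerate_grid()` produces it deterministically; `run_scan()` executes
any subset reproducibly, capturing per-pipeline failures with a reason
rather than aborting the scan.

## Score orientation

Continuous targets live on the ln(IC50) scale, where *lower* predictions
mean *more* sensitive; binarized targets use 1 = sensitive. Each
transformed response therefore carries an orientation flag, and
`orient_scores()` negates continuous-scale predictions before ROC/PR
evaluation so that a higher oriented score always means a more likely
responder. This convention is this package's resolution of an ambiguity
inherent in mixing regression and classification targets in one grid.

## The synthetic-data generator

`generate_paired_datasets()` creates a paired screen and cohort with
planted, recoverable structure:

* Cell-line expression is Gaussian per gene around a gene-level baseline
  \(\mu_g \sim N(7, 1.5^2)\) with unit within-gene spread, mimicking
  log-scale microarray intensities.
* A random subset of signal genes receives slopes
  \(\beta_g = \pm\,\texttt{effect\_size}/\sqrt{n_{\text{signal}}}\); the
  latent sensitivity of a sample is \(s = \sum_g \beta_g (x_g - \mu_g)\),
  so its variance is `effect_size`² regardless of the gene budget.
* Per drug, \(\ln IC50 = a_d - \big(f\,s + (1-f)\,s_d\big) + \varepsilon\)
  with a drug-unspecific general-sensitivity factor (weight
  `shared_fraction` = f), an independent drug-specific factor \(s_d\),
  and Gaussian noise. Pairwise correlation of noiseless drug responses is
  \(f^2/(f^2+(1-f)^2)\), which the tests verify against simulation.
* The cohort is treated with the screen's first drug, and its latent
  sensitivity mixes the shared and that drug's specific factor with the
  same weights. This is deliberate: if patients responded only to the
  shared factor, a model trained on the administered drug could never
  exceed a correlation of \(f/\sqrt{f^2+(1-f)^2}\) with the cohort's
  response even without noise, and no pipeline choice could recover the
  planted signal cleanly.
* Patient expression adds per-gene additive offsets
  \(\delta_g \sim N(0, \texttt{batch\_shift\_sd}^2)\) and multiplicative
  factors \(\lambda_g = e^{N(0,\,\texttt{batch\_scale\_sd}^2)}\) on the
  biological variation — the train-vs-test distribution shift that
  homogenization must remove. Responders are the patients whose
  (pre-batch) latent sensitivity exceeds the
  \(1-\texttt{responder\_fraction}\) quantile.
* Housekeeping genes have zero slopes but carry the batch offsets, so
  they are valid negative controls for the RUV methods; the landmark set
  contains a configurable share of signal genes, so the landmark filter
  can outperform or underperform by design.
* A fraction of gene ids is repeated as extra rows to exercise
  duplication handling. The duplicated ids are drawn from genes that
  carry no planted structure, so removing them — the pipeline removes
  every multiply-occurring name from both sides, it never averages —
  does not silently delete the signal the downstream tests recover.

Default sizes (1,000 genes, 150 cell lines, 30 patients, responder
fraction 0.45) mirror a realistic setting: screens of a few hundred
lines, clinical series of 24–169 patients with roughly balanced
responder splits. What the generator does **not** emulate: probe-level
artifacts, platform-specific intensity distributions, correlated gene
modules, tissue composition effects, or non-Gaussian heavy tails.
Passing tests therefore demonstrate internal correctness and qualitative
behaviour of the machinery, not expected performance on real cohorts.

## Numerical and design choices

* **Duplication handling precedes feature intersection**; both steps
  precede everything else.
* **Median splits**: values equal to the median go to the *sensitive*
  class for the cell-response cutoff (ties at lower ln(IC50)) and to the
  *non-responder* class for survival (conservative); both rules are
  deterministic.
* **1-D k-means** is solved exactly by scanning all split points of the
  sorted values for the minimum within-cluster sum of squares, removing
  any dependence on Lloyd initialization; the lower-centre cluster is the
  sensitive class.
* **Log/power-transform offset**: applied whenever the minimum response
  is ≤ 0 (not only strictly negative), since a zero minimum would
  otherwise hit log 0. The Box-Cox exponent is estimated by maximum
  likelihood (`car::powerTransform`).
* **Quantile normalization** uses the pooled mean quantile distribution
  of both batches, making the method symmetric in train and test.
* **The linear batch-term removal** equalizes per-gene batch means
  exactly; a constant shift added to one batch is absorbed into the
  batch term and changes the output only by a global constant.
* **ComBat** genes with zero variance in either batch cannot be
  standardized and pass through uncorrected with a warning. The residual
  batch gap after empirical-Bayes shrinkage is proportional to the
  within-batch noise; contract tests use a within-batch sd of 0.4,
  typical of per-gene replicate spread on a log2 scale.
* **RUV variants** default to 10 unwanted factors; the PCA variant
  regresses every gene on the top control-gene principal-component
  scores, the SVD variant removes the fitted span of the leading
  singular vectors of the centred control submatrix. Both leave
  residuals orthogonal to the estimated factors by construction. The
  factor count must be below the pooled sample count; it is reduced with
  a warning when the controls cannot support it.
* **The cumulative-proportion transform** requires non-negative input;
  pipeline runs enable a global min-shift because simulated log-scale
  expression is unbounded below. Descending ties are broken by gene
  index.
* **Gene-wise z-scoring uses training statistics only**, applied
  unchanged to the test side, preventing test-set leakage; sample-wise
  z-scoring is self-referential per sample by definition. PCA centres
  and rotations are fitted on training samples only.
* **The p-value filter** contrasts the most-sensitive and most-resistant
  25% of training samples (the two classes directly, for binary
  targets).
* **Ridge regularization** is chosen by 10-fold cross-validation like
  the other penalized fits, rather than a closed-form estimator.
* **Cell-to-cell cross-validation** binarizes the held-out truth by the
  pipeline's own binarization method, or at the median for continuous
  targets, so ROC is well defined for every pipeline.
* **Transfer experiment** splits cell lines 60/20/20 into
  train/validation/test.
* **Per-pipeline seeds** are derived deterministically from the base
  seed and the pipeline's stage choices, so scan results are invariant
  to configuration order and worker count.

## Statistical caveats the analyses surface

Two caveats deserve emphasis because the analysis scripts reproduce them
directly:

* **Small cohorts make noise look like skill.** The random-guessing AUC
  null has spread ≈ 0.10 at 24 patients but ≈ 0.04 at 169; a reported
  AUC of 0.7 on a 24-patient series is within two null standard
  deviations of chance.
* **Pipeline-level significance tests overstate certainty.** AUC values
  of thousands of pipelines evaluated on a *single* cohort realization
  are strongly dependent — well-performing pipelines produce nearly
  identical score vectors — so two-sample t-tests that treat pipelines
  as independent units (as in the transfer experiment's top-subset
  comparison) can flag differences of a few hundredths of an AUC as
  overwhelmingly significant. The transfer analysis therefore reports
  effect magnitudes alongside the p-values, and the magnitude contrast
  (large on the in-vitro test split, negligible on a confounded cohort)
  is the robust finding.

## Problem sizes

The test-suite and acceptance runs use reduced problem sizes chosen to
keep each property sharply testable: scans use 200-gene, 80-cell-line,
30-patient pairs with reduced forest sizes; signal-recovery checks use
300 cell lines against ~200 retained genes because unregularized least
squares — the simplest well-specified pipeline — only recovers planted
signal cleanly when samples exceed features; null calibrations use
10,000 draws. The analysis scripts under `analysis/` run moderately
larger versions of the same computations and write their tables under
`results/`.
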