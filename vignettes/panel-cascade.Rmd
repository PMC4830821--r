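---
title: "Hierarchical ROC scoring of biomarker panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical ROC scoring of biomarker panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelROC)
```

## The model

`panelROC` fits a three-level screening rule to a case--control cohort of
continuous biomarkers grouped into functional domains.

**Marker level.** For marker $j$ with abnormality direction $d_j \in
\{\text{high}, \text{low}\}$, the empirical ROC curve is built over all
observed thresholds (missing values excluded pairwise). The area under the
curve is computed by the mid-rank (Mann--Whitney) formula, which equals the
trapezoid area exactly and gives tied case--control pairs half credit. The
operating cutoff $c_j$ maximizes Youden's $J = \text{sens} + \text{spec} -
1$; it is reported as the midpoint between the adjacent observed values, so
the strict decision rule (value $> c_j$ for high, value $< c_j$ for low)
is unambiguous on the data the cutoff was fitted to.

**Domain level.** Marker flags are summed within each domain. The integer
tally is treated as a score in its own right and re-ROC'd over the integer
cutpoints $k = 1, \dots, \text{domain size}$ with the rule "domain abnormal
iff tally $\ge k$"; the Youden-optimal $k$ becomes the domain threshold. A
single-marker domain collapses to that marker's own flag with threshold 1.

**Model level.** Abnormal domains are counted per subject and the count
re-ROC'd the same way, giving the integer detection threshold $T$: a
subject is called a case iff at least $T$ domains are abnormal. The rule is
monotone by construction -- making any marker more abnormal can only raise
tallies, domain flags, the count, and hence never flips a predicted case
back to control.

Performance is recorded at all three levels: AUC with a two-sided
normal-approximation test of AUC $= 0.5$ using the Hanley--McNeil standard
error, sensitivity/specificity at the chosen threshold, the diagnostic odds
ratio $\mathrm{DOR} = \frac{s}{1-s}\cdot\frac{sp}{1-sp}$, and the accuracy
index (fraction correctly classified). Predictive values at an assumed
prevalence $\pi$ follow Bayes' rule,
$\mathrm{PPV} = s\pi / (s\pi + (1-sp)(1-\pi))$ and
$\mathrm{NPV} = sp(1-\pi) / ((1-s)\pi + sp(1-\pi))$; the DOR is
prevalence-invariant, which is why it is the portable effect measure for a
screening rule.

## Tunable parameters and conventions

* **Cutoff criterion** (`criterion`): `"youden"` (default) or
  `"closest.topleft"`. Youden ties are broken toward higher specificity --
  for a screening rule a tie costs nothing in $J$, and the stricter cutoff
  reduces false positives.
* **Integer-threshold tie rule** (`tieRule`): among equal-$J$ integer
  thresholds the smallest count wins (default), favoring sensitivity; the
  model is first a screening instrument. `"specificity"` flips this.
* **Prevalences** for predictive values default to $\{0.0035, 0.30\}$: a
  community prevalence of 0.35% for a psychosis-spectrum condition, and
  30% for an enriched clinical population.
* **Risk regression.** The logistic model $\operatorname{logit} p = a + b
  \cdot \text{count}$ is fitted by IRLS with convergence declared when the
  log-likelihood moves by less than $10^{-10}$ (hard cap 100 iterations);
  at the optimum the score equations $\sum (y_i - \hat p_i) = 0$ and
  $\sum x_i (y_i - \hat p_i) = 0$ hold to $10^{-8}$. Coefficients growing
  past $|\beta| > 30$ are treated as complete separation and flagged with a
  warning rather than reported as converged. The lowess smoother uses
  Cleveland's defaults -- tricube kernel over a window containing 2/3 of
  subjects, local linear fits, 3 bisquare robustness iterations -- with
  windows defined over subjects (the covariate has only $D+1$ distinct
  values), evaluation on the integer grid $0..D$, and fitted risks clipped
  to $[0, 1]$.
* **Imputation** defaults to the label-blind per-marker median: the method
  behind the original analyses is unrecorded, and a label-blind fill is
  the only choice that cannot leak group information into the completed
  table. The label-aware per-group median exists (`"groupMedian"`) solely
  to probe sensitivity to that unknown, and is flagged as such in its
  report.
* **Cross-validation** is class-stratified $k$-fold (default 5). The
  entire cascade -- marker cutoffs, domain thresholds, detection
  threshold -- is refit on each training fold by default; this is the
  honest-validation choice, and a `cutoffs = "frozen"` mode (marker
  cutoffs fixed from the full data, upper levels refit) is provided and
  labeled because either convention is defensible when replicating older
  analyses. The pooled summary concatenates test-fold predictions; the
  unweighted mean over folds is reported alongside because summary rows
  of this kind are conventionally ambiguous between the two.

## The synthetic cohort generator

Patient-level data for panels of this design are typically not available,
so every stage is exercised against generated cohorts with known ground
truth.

* **Binormal calibration.** Only AUCs are published for such panels, never
  per-marker distributions. Under the equal-variance binormal model the
  AUC alone determines the standardized case shift, $d = \sqrt 2 \,
  \Phi^{-1}(\mathrm{AUC})$ (`aucToEffectSize()`), so the generator is
  calibrated to AUCs and nothing else. Markers are produced on a
  standardized scale (control mean 0, sd 1); `low`-direction markers
  negate the shift rather than transform values, keeping units
  interpretable.
* **Within-domain correlation** comes from a single shared latent factor
  per domain: marker noise is $\sqrt\rho\, F_{\text{domain}} +
  \sqrt{1-\rho}\,\varepsilon$. One parameter ($\rho$, default 0.2) is all
  the published domain-coherent behaviour supports. The default was fixed
  once by matching study-scale (67 + 67, in-sample cutoffs) domain-level
  tally AUCs of the default panel to the reported domain performance:
  $\rho = 0.2$ reproduces the visual/auditory/catecholamine domain AUCs
  within a few hundredths, while $\rho = 0$ overshoots them.
* **Latent case intensity and functional measures.** A latent severity
  factor separates cases from controls by 2.35 sd (a severity ROC of about
  0.95, in line with the model-level discrimination of a well-calibrated
  panel). Each functional measure (SIR, GAF, CGI, SOFAS, admission rate,
  pension flag) is `severityLoading` (default 0.8) times the standardized
  latent intensity plus independent noise, mapped to conventional clinical
  scales (GAF/SOFAS inverted). The latent factor itself is stored in
  `colData$latent_severity` as ground truth for tests.
* **Missingness** is inserted completely at random, per marker, at the
  rate implied by each marker's published observation count
  ($(134 - n_{\text{obs}})/134$, between 0 and 9%). Only rates are
  reported for such panels, not mechanisms, so MCAR is the defensible
  default; values are masked as `NA`, never zero-filled.

**What the generator does not emulate:** assay-level realism (creatinine
adjustment, audiogram traces, instrument floors/ceilings), non-normal or
unequal-variance marker distributions, informative missingness, and
between-domain correlation beyond what caseness itself induces. Passing
tests therefore demonstrate that the cascade, its arithmetic and its
validation behave correctly under the stated statistical structure -- not
that any particular clinical panel will attain these operating
characteristics on real patients.

## Numerical choices and degenerate inputs

* Ties in the ROC receive half credit (standard Mann--Whitney convention);
  the AUC is computed from mid-ranks, which the test suite pins to
  exhaustive pair enumeration exactly on all small instances.
* The Hanley--McNeil test is mildly anticonservative at very small $n$
  (type-I error near 7% at $n = 30$ per group, 5--6% at study scale); it
  is the conventional approximation and its size at the cohort sizes the
  package targets is checked by simulation in the suite.
* Degenerate inputs fail loudly: single-class cohorts, all-missing
  markers/domains, constant logistic covariates and 100%-missing markers
  raise errors naming the offending level or marker; degenerate
  cross-validation folds are skipped with a warning.
* A subject's missing marker contributes nothing to a domain tally (it can
  only make the tally conservative); a tally is `NA` only when every
  member is missing. How to tally subjects missing an entire domain is
  genuinely open for this class of models -- treating an unobserved domain
  as not-abnormal is the screening-conservative reading, and imputation
  upstream (the default pipeline) makes the case moot.
* Lowess windows that collapse (all distances zero, or fewer than two
  points) fall back to weighted means / widened windows with a warning
  rather than a singular solve.
* In-sample optimism is real and visible: on null cohorts (all AUCs 0.5)
  the refit cascade's in-sample model AUC sits near 0.59 because
  Youden-optimal cutoffs chase noise. The package does not correct
  in-sample figures; it exposes the optimism through cross-validation,
  whose pooled null AUC is calibrated at 0.5 (checked by simulation).

## Problem sizes used by the test suite

The suite exercises cohorts of 134 subjects (the default configuration),
generator-calibration checks on replicate cohorts of 2000 subjects,
risk-model parameter recovery at $n = 10^4$, a 200-replicate study-scale
simulation of the full cascade (the fitted detection threshold lands at 3
of 5 abnormal domains in about 90% of replicates, model AUC ≥ 0.9), and a
50-replicate comparison of cross-validated against in-sample sensitivity
(the cross-validated mean tracks the in-sample mean within a few points).
These sizes were chosen so that every stochastic assertion sits several
Monte-Carlo standard errors inside its tolerance.

## Known limitations

* The cascade is strictly dichotomous; no weighted or continuous composite
  scores, by design -- interpretability at the bedside is the point of the
  tally rule.
* No variable selection: panel membership is configuration, not search.
* No smooth/parametric ROC fitting, partial AUC, or paired-AUC
  (DeLong-style) comparisons.
* Lowess fitted values on a 6-point integer grid depend on the realized
  label noise in each window; they are descriptive, not a parametric
  estimate, and are reported to mirror the conventional two-row
  logistic/lowess risk table.
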