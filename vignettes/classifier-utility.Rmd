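---
title: "From margin classifiers to clinical utility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From margin classifiers to clinical utility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmdx)
```

## The problem

Morphometric pattern classifiers for psychiatric disorders are usually
summarized by cross-validated accuracy. Accuracy alone does not tell a
clinician whether to order the test, how many patients must be tested per
correct prediction, or what a positive result does to the probability of
disease in a given population. `svmdx` implements the chain from
subject-by-feature case/control tables to exactly those quantities, together
with the synthetic data needed to test every stage without access to
clinical scans.

## The classifier

### Model

Given feature vectors $x_i \in \mathbb{R}^p$ with labels $y_i \in \{+1
(\text{control}), -1 (\text{patient})\}$, the soft-margin maximum-margin
classifier solves

$$\min_{w, b, \xi} \tfrac12 \lVert w \rVert^2 + C \sum_i \xi_i
\quad \text{s.t.} \quad y_i (w \cdot x_i + b) \ge 1 - \xi_i,\; \xi_i \ge 0,$$

equivalently the dual with box constraint $0 \le \alpha_i \le C$ and
$\sum_i \alpha_i y_i = 0$. A *linear* kernel is used throughout: with
$n \ll p$ (tens of subjects, hundreds to hundreds of thousands of features)
the $n \times n$ Gram matrix makes training cheap, and the primal weights
$w = \sum_i \alpha_i y_i x_i$ live in feature space, which is what makes
discrimination maps possible.

The dual is solved by sequential minimal optimization with
maximal-violating-pair working-set selection, written in C++. The solver is
deterministic (zero initialization, lowest-index tie-breaks) and stops when
the maximal Karush–Kuhn–Tucker violation falls below $10^{-10}$; the test
suite checks the resulting hyperplane against an independent quadratic
-programming implementation (libsvm via `e1071`) to $10^{-6}$ on small
two-dimensional fixtures. On fixtures with heavily overlapping classes the
dual has a nearly flat ridge and two fully converged solvers can differ by
about $10^{-6}$ in the hyperplane at identical objectives; one such fixture
is therefore compared at $10^{-5}$.

### Parameters and conventions

- **C (default 1).** The soft-margin constant is rarely reported in applied
  morphometry studies; 1 is the long-standing default of the libsvm family
  and is exposed everywhere as a parameter.
- **Label convention.** Controls are $+1$ ("class one", positive weights
  point toward controls), patients $-1$. For *diagnostic* indices the
  patient is the positive condition; the two conventions coexist
  deliberately, as they do in the field.
- **Tie rule.** A decision value of exactly zero predicts control: at
  equipoise the non-diagnosis is favoured. Configurable via `tie_label`.
- **Centering (default off).** Optional per-feature mean-centering uses
  statistics from the training rows only; inside LOSO the held-out subject
  never contributes to them.
- **Discrimination mask (fraction 0.30).** Features with weight at or above
  30% of the maximum positive weight (or at or below 30% of the most
  negative weight) are retained, the conventional threshold for displaying
  which regions drive the separation. The package emits index sets, not
  rendered maps.

### Cross-validation

Leave-one-subject-out: $n$ folds, subject $i$ predicted by a model fitted
without subject $i$. Results are invariant to input ordering (subjects are
canonicalized by ID before folding) and deterministic given the data and
C. A fold that would lose an entire class aborts with the offending subject
named — with 19 + 20 subjects this cannot happen, but it protects degenerate
inputs.

## Significance

**Permutation test.** Class labels are randomly reassigned (class counts
preserved — a permutation of the label vector, not i.i.d. relabeling) and
the *entire* LOSO pipeline is re-run per permutation; balanced accuracy,
sensitivity and specificity each get a null distribution. P-values use the
add-one estimator $p = (r+1)/(B+1)$, which is a valid test at any $B$. With
small cohorts the cross-validated statistics are heavily tied, so the test
is conservative: on null cohorts of 10 subjects the measured type-I error
sits at or below the nominal 0.05 (the acceptance suite measures it over
200 replicates of 99 permutations each).

**Paired t-tests** compare per-patient decision values between classifiers:
$t = \bar d / (s_d/\sqrt n)$, $df = n - 1$, two-sided. The formula is
implemented directly so that zero-variance differences raise an explicit
degenerate-input error instead of returning $\pm\infty$; agreement with
`stats::t.test` to $10^{-10}$ is part of the test suite.

**Cohen's kappa** between two classifiers' predicted labels uses the
standard marginal-frequency expected agreement.

## The clinical-utility panel

From the confusion matrix (patient positive): sensitivity, specificity,
balanced accuracy $=(\text{sens}+\text{spec})/2$, PPV, NPV, and

$$\mathrm{PSI} = \mathrm{PPV} + \mathrm{NPV} - 1, \qquad
\mathrm{NNP} = 1/\mathrm{PSI}, \qquad
\mathrm{DOR} = \frac{TP \cdot TN}{FN \cdot FP}
 = \frac{\text{sens}/(1-\text{sens})}{(1-\text{spec})/\text{spec}}.$$

NNP is undefined (flagged, not an error) when $\mathrm{PSI} \le 0$; a zero
cell makes the DOR infinite unless the opt-in 0.5 continuity correction is
enabled (off by default — the default group sizes produce no zero cells).

### Rounding policies

Published tables usually round rates to one decimal percent *before*
deriving the composite indices, and the composites only reproduce if the
same chain is followed. Two policies are therefore provided:

- `"exact"`: full precision; DOR from the integer counts.
- `"published"`: rates rounded to one decimal percent; PSI, NNP and DOR
  computed from the rounded proportions and reported to three decimals.

`confusion_from_rates()` closes the loop from a printed
sensitivity/specificity back to integer counts (nearest integer at the
stated group sizes, warning when two counts are equally near). Worked
example, reproducing a published reporting chain exactly:

```{r}
panel <- utility_panel(confusion_from_rates(0.789, 0.75, 19, 20), "published")
unlist(panel[c("PPV", "NPV", "PSI", "NNP")])
```

A caution this package's tests document: composite cells in published
tables are not always internally consistent. For the four classifier rows
used in the acceptance suite, the printed PSI/NNP values reproduce exactly
under the `"published"` chain, but the printed DOR cells do not follow from
their own printed sensitivity/specificity under any rounding we examined
(one of them is inconsistent by a factor of ~1.17). The suite asserts the
exact count-based values (e.g. $15 \cdot 15/(4 \cdot 5) = 11.25$) and
records the discrepancy rather than reproducing arithmetic that cannot be
derived.

## Bayesian post-test probabilities

For a test with operating characteristics $(\text{sens}, \text{spec})$ and
prior prevalence $\pi$:

$$P(D \mid +) = \frac{\pi\,\text{sens}}{\pi\,\text{sens} +
(1-\pi)(1-\text{spec})}, \qquad
P(D \mid -) = \frac{\pi(1-\text{sens})}{\pi(1-\text{sens}) +
(1-\pi)\,\text{spec}}.$$

Several tests that *all* return positive combine on the odds scale:
posterior odds $= \frac{\pi}{1-\pi} \prod_k
\frac{\text{sens}_k}{1-\text{spec}_k}$, under the assumption of conditional
independence given disease status — an assumption the package states but
cannot check. Only the all-positive rule is implemented; an any-positive
rule is a documented extension point.

Decisions compare the posterior against two thresholds, defaulting to 0.85
(treat) and 0.45 (discharge), inclusive at the boundary. Source material
for this scenario gives 0.85 in one place and 0.80 in another; 0.85 was
fixed as the default and both thresholds are plain arguments. Boundary
operating characteristics (specificity 1, sensitivity 0 or 1) return the
stated limits with flags instead of raising errors.

The analogous single-test posteriors at $\pi = 0.70$ for the strongest
classifier row evaluate to $88.0\%$ (positive) and $39.6\%$ (negative)
under the exact formulas; the test suite asserts these exact values, noting
that rounded variants circulating with the same scenario (89%/42%) are not
obtainable from the stated operating characteristics.

## The synthetic paired cohort

### What it emulates

Two groups (19 patients, 20 controls by default) measured twice — a
noisier low-field and a cleaner high-field acquisition of the same
anatomy. The generative model for subject $i$, feature $j$, field $f$:

$$x_{fij} = g_i + a_{ij} - \delta_{ij}\,\text{effect} + \epsilon_{fij},
\qquad g_i \sim N(0, \tau^2),\; a_{ij} \sim N(0,1),\;
\epsilon_{fij} \sim N(0, \sigma_f^2),$$

where $\delta_{ij} = 1$ for patients on the first $\lceil \text{fraction}
\cdot p \rceil$ features (a contiguous leading block, so tests know the true
effect indices) and 0 otherwise.

### Why the global-size factor exists

A pure latent-plus-noise model cannot simultaneously produce (a) a
between-field correlation of per-subject feature totals near 0.93 — the
calibration fact the generator is built to reproduce — and (b) noise large
enough that field strength matters for classification: with independent
features the total-sum correlation is $1/\sqrt{(1+\sigma_l^2)(1+\sigma_h^2)}$,
forcing $\sigma \lesssim 0.35$ and making the field difference negligible.
Real morphometry has a subject-level overall-volume factor shared by every
feature; adding it ($g_i$, default $\tau = 0.13$) decouples the two
requirements. With $p = 500$ features and noise scales $\sigma_l = 1.0$,
$\sigma_h = 0.5$, the analytic total-sum correlation is

$$\frac{p^2\tau^2 + p}{\sqrt{(p^2\tau^2 + p + p\sigma_l^2)
(p^2\tau^2 + p + p\sigma_h^2)}} \approx 0.94,$$

which the acceptance suite confirms empirically (averaged over 20 seeds).
Because noise is mean-zero in both fields, paired comparisons of the totals
show no systematic field offset; and because the group effect (default
block of 50 features shifted by 0.6) is small against the total-sum spread,
the groups do not separate on total volume — both properties of the data
the generator stands in for.

### Defaults and their rationale

| parameter | default | rationale |
|---|---|---|
| `n_patients`, `n_controls` | 19, 20 | the cohort size of the study design emulated |
| `n_features` | 500 | large enough for $n \ll p$ behaviour, small enough for fast tests |
| `effect_fraction` | 0.1 | a diffuse multivariate effect, not a single marker |
| `effect_size` | 0.6 | no published effect size exists for this design; 0.6 puts the default LOSO balanced accuracy in the high-60s to high-70s percent band that such classifiers report, with the high field a few points above the low field |
| `noise_scale_low_field`, `noise_scale_high_field` | 1.0, 0.5 | high field ≈ double SNR; with $\tau = 0.13$ the total-sum correlation lands near 0.93 |
| `global_scale_sd` ($\tau$) | 0.13 | see formula above |

All randomness flows from one integer seed. Base R has no counter-based
generator, so order-independence of the draw blocks is achieved by deriving
one sub-seed per block (latent anatomy, low-field noise, high-field noise)
from the master seed and drawing each block under its own temporarily-set
RNG state; identical configurations are bit-identical, and the two tissue
cohorts of the comparison pipeline get independent sub-seeds the same way.

### What passing tests do and do not show

The generator produces Gaussian, feature-independent (conditional on $g_i$)
data with a block effect. Real morphometry is spatially smooth, heavy-tailed
at segmentation boundaries, and its field-strength differences are not
purely additive noise (bias fields, contrast changes). Tests passing on this
synthetic family demonstrate that the pipeline's *machinery* is correct and
calibrated — not that any particular accuracy will transfer to scanner data.

## Problem sizes used by the test and acceptance suites

Cross-validation properties use cohorts of 8–39 subjects with 5–500
features; the permutation type-I study uses 200 replicates of 10 subjects
× 20 features at 99 permutations; utility identities are verified by
exhaustive enumeration of all confusion matrices with total count ≤ 12;
Bayes identities on 1,000 random (prior, sens, spec) triples. These sizes
keep the full suite under a few minutes on one CPU while leaving every
statistical check with comfortable Monte-Carlo margins.

## Known limitations

- Linear kernel only; no probability calibration, no multi-class, no ROC
  analysis (the decision threshold is fixed at zero).
- Confidence intervals for DOR/NNP are not provided.
- The all-positive combination rule assumes conditional independence of the
  combined tests; violations inflate the combined posterior.
- The permutation test permutes labels once per replicate before the full
  LOSO run (the standard reading of label permutation for cross-validated
  statistics); per-fold permutation schemes are not implemented.
- Feature tables are the native input. Imaging users must vectorize volumes
  upstream; a flattened voxel vector per subject maps one voxel to one
  column.
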