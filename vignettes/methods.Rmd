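---
title: "Cross-cohort sub-classification of mild TBI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort sub-classification of mild TBI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbisubclass)
```

## The problem

Mild traumatic brain injury (GCS 13–15 at emergency-department arrival,
closed head injury) is clinically heterogeneous: patients with the same
GCS band differ widely in demographics, injury mechanism, imaging findings
and eventual recovery. `tbisubclass` implements a cross-study workflow for
finding data-driven sub-classes of such patients from the clinical
variables available at the initial ED evaluation, and for asking the
question that makes sub-classes clinically meaningful: *do the same
sub-classes reappear in an independent cohort, and do they stratify
90/180-day outcomes?*

The workflow is: encode the clinical table against a declared schema →
impute missing values by chained equations, per cohort → sparse
hierarchical clustering of the discovery cohort → per-sub-class centroids
→ nearest-centroid classification of the validation cohort → retention of
the well-populated sub-classes → reproducibility scoring (in-group
proportion, centroid profile correlation, outcome-proportion agreement) →
sub-class-conditional outcome tests and PPV/NPV prognosis. Because the
motivating datasets are access-restricted, the package ships a synthetic
twin-cohort generator with known ground truth; every stage is validated
against it.

## Clinical variable schema

The packaged schema (`tbi_schema()`) declares 37 variables in seven
categories (demographics, medical history, injury mechanism, ED
examination, blood work, vital signs, complications). Binary variables are
coded 0/1, ordinal variables 1..L, and the two GCS scores stay numeric
(13–15 at arrival after inclusion, 3–15 at discharge). Raw vital signs are
converted to ordinal codes by `bin_vital()` with the band conventions
taken literally from their clinical definitions: "less than x" is
$[-\infty, x)$, "at least y" is $[y, \infty)$, and the middle band is
closed on both printed endpoints. Temperature is the one variable whose
top band is "greater than" its cut point, so 37.7 °C itself is *normal*;
the schema records this with an `upper_open` flag.

Variables enter the analysis only if they are present in both cohorts with
under 10% missing values in each (`missingness_filter()`), with a
declared exception list for variables judged exceptionally important
(post-traumatic amnesia duration and pupil reactivity in the packaged
schema). Missing cells are empty CSV cells; sentinel codes are rejected,
because a sentinel that is also a legal code is silent data corruption.

## Imputation

`impute_cohort()` is a chained-equations (fully conditional specification)
imputer: initialize missing cells by draws from each variable's observed
marginal, then cycle through incomplete variables (least missing first),
regressing each on all other variables over its observed rows and
redrawing its missing cells from the fitted conditional — logistic
regression with a Bernoulli draw for binary variables, multinomial logit
with a categorical draw for ordinal ones, and a linear model with a normal
residual draw (rounded, clamped to the legal range) for numeric ones. A
model that fails to fit — perfect separation is routine in small binary
tables — falls back to a marginal draw, keeping the sweep robust.

Defaults: 10 sweeps, one completed dataset. A single completed matrix is
what downstream clustering consumes; multiple imputations remain available
(`n_imputations`) for sensitivity runs, but pooling across completions is
deliberately out of scope — imputation here serves clustering, not
inference. Each cohort is imputed separately; pooling cohorts before
imputation would leak distributional information across the discovery /
validation boundary.

Two properties are enforced and tested: observed cells are never altered,
and with informative predictors the mask-and-recover accuracy beats the
majority-class baseline. Note that *draws* from a fitted conditional are
the right thing for preserving distributions but are not the accuracy-
maximizing point prediction; on pure-noise variables the majority baseline
is slightly better by construction. The gain therefore comes entirely from
the structured variables, which is exactly what the paired-baseline test
measures.

## Sparse hierarchical clustering

The core model is feature-weighted agglomerative clustering. For patients
$i < i'$ and feature $j$, the dissimilarity decomposes additively as
$d_{(i,i'),j} = (x_{ij} - x_{i'j})^2$ on features standardized to zero
mean and unit variance within the cohort (mixed binary/ordinal codes have
no common scale otherwise; an absolute-difference variant is available).
Collecting the pairs in a matrix $D \in \mathbb{R}^{\binom{n}{2} \times p}$,
the fit solves

$$
\max_{w, u} \; \sum_j w_j \, (u^\top d_{\cdot j})
\quad \text{s.t.} \quad \|u\|_2 \le 1, \; \|w\|_2 \le 1, \;
\|w\|_1 \le s, \; w \ge 0,
$$

by alternating closed-form updates: $u \propto D w$ and
$w = S(D^\top u, \Delta) / \|S(D^\top u, \Delta)\|_2$, where
$S(a, \Delta) = \max(a - \Delta, 0)$ is the soft threshold and $\Delta$ is
0 if the L1 bound is slack, otherwise found by bisection so the bound
binds. Equivalently the problem is $\max_w \|Dw\|_2$ over the constraint
set, which is what the package's dense grid-search oracle checks at
$p \le 3$. The objective is non-decreasing across iterations (asserted in
tests); iteration stops when the relative objective change falls below
`tol` (default `1e-5`, cap 200 alternations). At $s = 1$ the optimum is a
single feature (the one with the largest dissimilarity-column norm); at
$s = \sqrt{p}$ the bound is vacuous and exchangeable features get uniform
weights.

The L1 bound $s$ is tuned by a permutation gap criterion
(`tune_sparsity()`): each variable's values are independently shuffled
across patients — preserving marginals, destroying joint structure — and
$\mathrm{Gap}(s) = \log O(s) - \overline{\log O_b(s)}$ is maximized over a
default grid of 10 log-spaced candidates in $[1.1, \sqrt{p}]$ with
$B = 10$ permutations (ties to the sparser bound). On the two-class
benchmark the gap curve peaks exactly at the bound that selects the
planted informative variables. Variables with nonzero tuned weight are
reported as the ones that "significantly contribute" to the
sub-classification; the sparsity pattern is the only selection criterion.

The tree is built by `stats::hclust` on the weighted dissimilarity
$\sum_j w_j d_{\cdot j}$ and cut into $K$ groups from the top $K-1$
merges; groups are renamed A, B, … by decreasing size (ties by first
patient index). $K$ is fixed by configuration (default 7, the number of
sub-classes the motivating analysis reported in both cohorts); the package
deliberately offers no automatic selection of $K$.

**Linkage.** The design was genuinely open here and the package default is
*average* linkage, not complete. On coded clinical data the weighted
dissimilarity takes few distinct values, and complete linkage — whose
merge heights jump to the cluster diameter immediately — degrades to
near-arbitrary top-level splits under the resulting ties. On the two-class
generator benchmark, complete linkage essentially never recovers the
planted partition while average linkage does so reliably; the tests
encode this benchmark. Complete linkage remains available
(`linkage = "complete"`), and with uniform weights either linkage
reproduces `stats::hclust` on the plain metric label-for-label, which is
the package's equivalence oracle.

A residual limitation worth stating: even with well-chosen weights, cut
labels from an agglomerative tree misplace a few boundary patients that a
nearest-centroid rule would classify correctly (on the two-class benchmark
the adjusted Rand index against truth levels off around 0.9, with a
nontrivial minority of replicates just below it). This is a property of
tree cutting on discrete profiles, not of the weight optimization.

## Transfer and reproducibility

`compute_centroids()` averages each clinical variable over the patients of
each sub-class (binary variables become proportions, ordinals mean codes)
over a declared variable set — by default the SHC-selected variables,
matching the profiles a clinician would compare; all-variable and
weighted-distance variants are configurable. Centroids live on the raw
code scale so they remain clinically readable.

`classify_by_centroid()` assigns each validation patient to the nearest
centroid (Euclidean, ties to the alphabetically first class). A sub-class
that receives no patients is flagged as not reproducible outright. The
`retention_rule()` then focuses the analysis on the minimal set of largest
classes jointly covering at least 95% of the validation cohort — the
operational form of "focus on the well-populated sub-classes"; 0.95
reproduces the published retention decisions when applied to the published
assignment counts, which is exactly what the acceptance script recomputes.

Three reproducibility scores are reported per retained class:

* **In-group proportion** (`compute_igp()`): the fraction of a class's
  validation patients whose nearest neighbor *within the validation
  cohort* shares the class. Computed with the same distance and variable
  set as the classification; verified against an exhaustive $O(n^2)$
  oracle, invariant to relabeling and to common rescaling of all
  variables. Under labels shuffled independently of geometry its
  expectation is $(n_k - 1)/(n - 1)$, which the tests check — a useful
  reminder that IGP must be read against class size.
* **Profile correlation** (`profile_correlation()`): Pearson r (with
  two-sided p from `stats::cor.test`) between the discovery centroid and
  the empirical centroid of the validation patients classified into the
  class, over the shared variable set. Zero-variance profiles are
  reported as undefined rather than silently dropped.
* **Outcome agreement** (`outcome_agreement()`): per class and instrument,
  a two-sample pooled-variance proportion z-test of the bad-outcome
  fraction, discovery class vs validation class, complete cases per
  instrument. No continuity correction by default, matching the plain
  two-sample z formulation; the corrected variant is a flag. The
  uncorrected test's true size is a shade above the nominal 5% at cohort
  scale (the normal approximation is mildly liberal), so calibration
  checks in the test suite use the corrected variant — a reporting
  choice, not a change to the pipeline default.

## Outcomes and prognosis

Five instruments are binarized to good/bad (`binarize_outcomes()`):
GOSE at 90 and 180 days (1–7 bad, 8 good); BSI at 180 days (bad iff the
Global Severity Index T-score exceeds 63 or at least two subscale
T-scores do — both strict); WAIS (bad iff at or below one SD below the
norm mean, default 100/15 — the norm is configurable because no single
composite is universal); TMT (bad iff either part's age-adjusted
normalized time is at or above one SD above the mean; TMT values are
expected as z-scores, raw-time normalization tables being out of scope).
Partial missingness propagates conservatively: a rule returns bad as soon
as any observed component establishes it, good only when all components
needed to rule bad out are observed, and missing otherwise.

Between-class differences use one-way ANOVA on the 0/1 coding
(linear-probability ANOVA; for two classes this is exactly the pooled
t-test squared, which the tests assert) and pairwise 2×2 chi-square tests
without Yates correction, raw p-values by default with Holm as an option.
Prognosis conditions within sub-class: PPV is the probability that a bad
90-day GOSE stays bad at 180 days, NPV that a good 90-day GOSE stays
good; both are reported with numerators and denominators, and the two
denominators partition each class's complete cases. The pooled analysis
concatenates discovery labels and validation assignments before testing,
so both cohorts contribute to each retained sub-class.

## The synthetic twin-cohort generator

`generate_pair()` draws two cohorts from `k` shared latent classes.
Informative variables get class-specific categorical distributions; noise
variables a single marginal; outcomes are Bernoulli draws from a
class-by-instrument bad-probability matrix, rendered as raw instrument
scores that binarize back to the drawn status. Missingness is MCAR at a
configurable cell rate (default 5%, inside the 10% retention rule); MAR
mechanisms are a deliberate non-goal because the motivating analysis does
not characterize its missingness. Ordinal variables are drawn directly
over their codes rather than by thresholding a latent continuum — the
simplest structure consistent with the schema.

Two presets define the package's study conditions. `two_class`: 200
patients per cohort, 5 informative binary variables whose yes-probability
alternates 0.9/0.1 across variables (so each class has a distinctive,
non-flat profile — a flat profile would make centroid correlations
degenerate), 20 noise variables at 0.5. `paper_like`: 478 and 564
patients, 7 classes with the reported mixing proportions, the full
37-variable schema with 11 informative variables carrying distinct on/off
profiles and 26 noise variables at cohort-scale frequencies. The optional
`shift` perturbs selected classes in cohort B only, moving each
probability row toward its reverse by `delta`; `delta = 0.5` (the midpoint
between intact and fully reversed) is the package's standard setting for
"this class should fail to reproduce" experiments — a full reversal can
turn one class into an alias of another, which tests aliasing rather than
non-reproducibility.

What the generator does *not* emulate: within-class correlation beyond
what class membership induces, MAR/MNAR missingness, measurement drift
between cohorts, and the real datasets' joint correlation structure.
Passing tests on synthetic pairs therefore demonstrate correctness of the
machinery and recoverability under the stated conditions, not performance
on real clinical data.

## Numerical choices and degenerate inputs

* Bisection for the soft-threshold level runs 60 halvings and zeroes
  weights below $10^{-10}$ of the maximum (the bisection otherwise leaves
  $O(\varepsilon)$ residuals that would inflate the support).
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so every artifact is bit-reproducible; the pipeline never mutates its
  inputs.
* Constant columns standardize to all-zero contributions rather than
  dividing by zero; fully-missing variables are refused with instructions
  to exclude them; empty sub-classes are an error for centroids, a skip
  with notice for outcome tests, and "not reproducible" for transfer.
* Distance ties (classification and nearest neighbors) resolve to the
  first index / alphabetically first class, keeping every run
  deterministic.
* Test and acceptance problem sizes are the presets' own: 200-patient
  cohorts for recovery and calibration loops (10–20 replicates), the
  478/564-patient pair for one full pipeline run. These sizes keep the
  whole suite at desk scale while leaving the class-recovery and
  calibration questions statistically meaningful.

## Known limitations

Tree-cut label recovery lags nearest-centroid accuracy on discrete
profiles (see above). The number of sub-classes is an input, not an
inference. IGP is reported raw, without a permutation significance
calibration. The imputer is a single-chain FCS without Rubin pooling. The
generator's independence assumptions make its cohorts easier to cluster
than real clinical tables at the same separation; treat synthetic
recovery rates as upper bounds.
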