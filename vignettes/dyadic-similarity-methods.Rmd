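---
title: "Methods: dyadic neural similarity and JZS Bayes factor model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic neural similarity and JZS Bayes factor model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadisc)
```

This vignette documents the statistical model behind `dyadisc`, the
assumptions it makes, the choices taken where the design was genuinely
open, and what the synthetic-data tests do and do not establish about real
data.

## Neural similarity

For each dyad, both partners' preprocessed BOLD series are reduced to
parcel-mean timecourses: within each atlas parcel the series is averaged
over voxels whose timecourse is not identically zero. We read "non-zero
voxels" as *mask-excluded voxels carry an all-zero timecourse*, the usual
semantics of preprocessed BOLD, rather than per-volume non-zero values;
a per-volume rule would make the averaging basis vary over time. Parcels
with no eligible voxel yield a flagged all-missing column instead of an
error, because atlas parcels can fall outside a subject's field of view.

Each run is then trimmed — the first 21 volumes and all volumes after the
stimulus ends are discarded — and the retained runs are concatenated in run
order. Region-wise similarity is the Pearson correlation of the two
partners' columns, computed volume-for-volume on that concatenated matrix;
whole-brain similarity is the unweighted mean of the region profile and a
parcel-size-weighted mean is reported alongside. Motion similarity is the
Pearson correlation of the partners' framewise-displacement series over the
*same* retained, trimmed volumes (a flagless design choice: correlating
untrimmed FD would misalign it with the data actually entering the ISC).

Three alignment/bookkeeping rules deserve comment:

* **Run intersection.** When partners retain different run sets, similarity
  is computed only over runs retained by *both*, aligned volume-wise. Any
  other pairing would correlate rows recorded under different stimuli.
* **Exclusion rule.** A subject with more than two flagged runs is excluded
  outright; with one or two, only those runs are dropped and the minutes of
  usable data are recomputed from the retained post-trim volumes times the
  TR.
* **Constant regions.** A constant column makes the Pearson correlation
  undefined; such regions are set to missing and excluded from both means
  (silently imputing zero would bias the whole-brain mean downward), with
  the dropped count reported.

## Behavioral measures

Communicative success is the mean absolute distance between guess and
hidden bullseye (0–100) over the trials in which the participant was the
guesser; clue-giver trials are ignored. For "higher is better" displays the
score is negated rather than subtracted from 100: only the ordering matters
for correlation and Bayes-factor analyses, and negation needs no assumption
about the score's range. Perceived interaction quality is the sum of three
1–5 Likert items (range 3–15). Trait questionnaires are scored as plain
(reverse-keyed) item sums with optional subscale index sets, and partner
similarity on a questionnaire is the item-level Pearson correlation between
the two partners' response vectors. Participants missing a measure are
dropped listwise from each test that uses it; nothing is imputed.

## The JZS Bayes factor

Each model is compared against the intercept-only null through

$$\mathrm{BF}_{10} = \int_0^\infty (1+g)^{(n-p-1)/2}
  \bigl(1 + g(1-R^2)\bigr)^{-(n-1)/2} \pi(g)\, dg,$$

where $R^2$ is the classical coefficient of determination of the model and
$\pi(g)$ is the inverse-gamma$(1/2,\ n r^2/2)$ mixing density that makes
the implied prior on standardized effects a Cauchy with scale $r$. The
default $r = \sqrt{2}/4$ for continuous terms is the conventional "medium"
anchor for psychological data; factor terms use $1/2$. The integrand was
verified against the published JZS correlation Bayes factor (the $p = 1$,
$r = 1$ special case) and against the package's own Monte-Carlo estimator;
the unit tests pin both routes to independently computed reference values.

Design construction: continuous predictors are z-scored; a factor with $L$
levels enters through orthonormal sum-to-zero contrasts ($L-1$ columns);
an interaction is the elementwise product of its standardized continuous
parents, restandardized so the prior scale keeps its meaning. All columns
are centered, and $n > p + 2$ is required so the integral is proper.

**Single shared g.** All columns of a model share one $g$, with mixed
continuous/factor designs blended through an effective scale
$r_\mathrm{eff}^2 = \tfrac1p \sum_j r_j^2$. Reference implementations
sometimes give factors their own $g$; that multiple-$g$ treatment is out of
scope here, and this is a documented, deliberate deviation. Its practical
consequence is a possible shift in absolute BF values for models containing
the confederate factor — which is why the package's contracts are stated in
terms of model *rankings*, relative BFs and recovery rates, and why
`prior_sensitivity()` reports rankings across a candidate set per scale so
stability under the prior can be checked directly.

**Numerics.** Quadrature integrates the log integrand on $t = \log g$: both
the inverse-gamma spike near $g \approx n r^2/2$ and the likelihood bump
near $g \approx n$ are $O(1)$ wide on the log scale at *every* prior scale,
so adaptive quadrature (relative tolerance $10^{-8}$, range truncated where
the integrand falls $e^{-60}$ below its peak) resolves them even for scales
near zero, where a $g/(1+g)$ compactification squeezes the spike into an
unresolvable sliver. The Monte-Carlo route draws
$g = b/\mathrm{Gamma}(1/2)$ and averages the likelihood-ratio term in the
log domain, reporting the relative standard error of the mean; with a fixed
seed it is bit-reproducible. If quadrature fails to converge the engine
falls back to Monte Carlo with a warning. $R^2$ numerically at 1 is an
error (degenerate likelihood); the null model returns $\mathrm{BF} = 1$
exactly.

Known limiting behavior, all tested: BF < 1 whenever $R^2 = 0$; BF strictly
increasing in $R^2$ at fixed $(n, p)$; BF invariant under affine transforms
of predictors or outcome; and BF $\to 1$ as the prior scale $\to 0$, with
the deviation decaying *linearly* in the scale — the tests therefore assert
monotone decay down to scale $10^{-6}$ rather than an arbitrarily tight
tolerance at a larger scale.

## Comparison workflow

Per outcome and per measure category, every subset of the candidate
measures (there are $2^m$, including the empty set) is augmented with the
fixed covariates and scored. Covariate rules: the confederate factor enters
every model, including the baseline; the number of retained runs and motion
similarity enter whenever neural similarity (whole-brain or region-wise) is
among the candidates, and only then — quality comparisons without an ISC
candidate carry the confederate alone. The relative Bayes factor of a model
is its BF divided by the covariates-only BF, so the baseline's relative BF
is exactly 1. Listwise deletion is applied once over the comparison's full
variable set, not per model, so every model in a table is fit to the same
rows and the BFs are comparable.

The best single-measure model per category selects the measure for the
follow-up interaction test (exact ties break to the more parsimonious
model, then lexically, with a warning); the interaction test evaluates the
baseline, both single main effects, the additive model, and the full model
with the product term, and reports the additive-over-interaction BF ratio.
The region-wise analysis refits the winning model once per region with that
region's ISC substituted for the whole-brain term, reporting per-region BFs
and BF > 3 / BF ≥ 10 flags. No multiplicity correction is applied — the
output is labeled exploratory, and the thresholds are descriptive bands,
not error-controlled decisions. Whether complete cases should be re-selected
per region is ambiguous; the pipeline reuses one case set per comparison so
the per-region BFs remain comparable.

Evidence bands follow the conventional scheme — below 1 against, 1–3
anecdotal, 3–10 moderate, 10–100 strong, above 100 extreme — with
boundaries left-closed at 3 and 10, and 100 still counted as strong.

## The synthetic dyad generator

The generator's defaults encode the study design the package targets: 268
parcels, four runs of 320 volumes at a 2 s TR with 21 volumes trimmed and
the stimulus ending at volume 300, eight confederates shared round-robin
across 60 participants with the scanner-pairing constraint, and a per-run
dropout probability of 0.05 (so roughly the observed handful of subjects
lose runs, a few cross the >2-run exclusion threshold in larger samples).

* **BOLD model.** Per region, participant signal is
  $\sqrt{\rho}\,s + \sqrt{1-\rho}\,e$ with the partner sharing $s$, so the
  expected region-wise correlation equals the dyad's configured
  shared-signal fraction $\rho$. All components are stationary unit-variance
  AR(1) series ($\phi = 0.4$): the cheapest structure that gives the
  realistic temporal autocorrelation a correlation-based pipeline must
  survive. Dyad-level $\rho$ is drawn uniformly from $(0.01, 0.3)$ by
  default — whole-brain ISC in naturalistic viewing is modest — but this
  range is a placeholder, not a calibration to any particular sample.
* **Confederate scans.** Each confederate's timecourse is re-simulated per
  dyad rather than fixed per confederate. Real confederates are scanned
  once; fixing their series would induce correlations between dyads sharing
  a confederate that the analysis does not model. The confederate's
  systematic influence is instead carried by the outcome offsets below.
* **Outcomes.** Game distance is
  $\text{baseline} - c\sum_k \beta_k z_k + c\,(\text{confederate offset} +
  \varepsilon)$, clipped to $[0, 100]$: standardized effects
  ($\beta_{\text{similarity}} = \beta_{\text{IRI}} = 0.5$, residual SD 1,
  confederate offsets drawn once per confederate with SD 0.5) scaled by
  $c = 10$ points per standardized unit around a baseline of 30 so the
  numbers look like game scores. The scaling is cosmetic — the BF analysis
  is affine-invariant. Perceived similarity is an ordinal 1–5 item whose
  latent is, by default, *uncoupled* from neural similarity (the two
  similarity measures are modeled as distinct signals); perceived quality
  is discretized from a latent driven mostly by perceived similarity
  ($\gamma = 0.7$) with a small mind-reading-motivation term
  ($\gamma' = 0.15$), rounded into the 3–15 composite range — the composite
  is treated as numeric downstream, so rounding the latent is the simplest
  honest discretization.
* **Trials.** The trial-level game data realize each participant's target
  distance exactly up to the 1/15-point quantization a 15-trial mean
  imposes, and the outcome table is kept consistent with its own trial
  realization.
* **Seeding.** One master seed; every stage (ISC draws, BOLD, dropouts,
  traits, outcomes, trials) derives its own sub-stream deterministically,
  so regenerating any piece is reproducible without replaying the rest.

**What passing tests show — and do not.** The generator produces Gaussian
AR(1) parcel series with a uniform shared-signal fraction across regions,
independent FD, and linear outcome structure. Tests against it establish
that the pipeline's arithmetic, alignment, exclusion logic and inference
behave correctly under the assumed model: configured similarity is
recovered in rank (ρ > 0.95 across 50 dyads), planted additive effects are
identified as the winning model in ≥ 80% of replicates at n = 60, and the
null produces baseline wins and median BF < 1. They do not establish
robustness to hemodynamic nonstationarity, voxel-level artifacts,
physiological noise, non-Gaussian outcome distributions, or regionally
heterogeneous coupling — real-data properties the generator deliberately
does not emulate.

## Problem sizes

The package's own test and reproduction runs use reduced imaging sizes
chosen to exercise every code path at desk scale: 10–15 regions, single
runs of 1,500–10,000 volumes for correlation-accuracy checks (the Fisher
standard error at T = 10,000 makes ±0.02 a meaningful bound), 50-dyad
recovery sweeps, 100–200 replicate simulations for rate and median
checks, and full-pipeline runs at 60 dyads × 10 regions. Quadrature makes
each Bayes factor effectively instantaneous, so the replicate counts are
set by statistical, not computational, considerations.

## Known limitations

* Single shared $g$ for mixed designs (see above); absolute BFs for
  factor-containing models may differ from multiple-$g$ implementations.
* Volume-space atlases only; no surface parcellations, no lagged or
  windowed ISC variants.
* The generator does not calibrate its similarity distribution to any
  empirical sample, and confederate scans are independent across dyads.
* Mixed (random-effect) JZS models, posterior sampling of coefficients and
  model averaging are out of scope.
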