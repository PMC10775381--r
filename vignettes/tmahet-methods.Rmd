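---
title: "Methods: H-score heterogeneity analysis for TMA cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: H-score heterogeneity analysis for TMA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmahet)
```

`tmahet` analyses immunohistochemical cell-surface target expression in
multi-site tumor cohorts sampled on tissue microarrays, as collected by
rapid-autopsy programs in metastatic castration-resistant prostate cancer.
This vignette is the package's account of its statistical methods: the
models, the defaults and why they are what they are, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate.

## Scoring model

Each TMA core is scored at three staining intensities (0 none, 1 faint, 2
prominent) as percentages of cells `p0, p1, p2` summing to 100. The H-score
is the intensity-weighted sum `0·p0 + 1·p1 + 2·p2`, ranging 0–200. A core
is *positive* when H ≥ 20; the boundary is inclusive, and the same single
cut-off is applied to every marker (TROP2, PSMA, DLL3, CEACAM5 and the
subtype markers alike). Precomputed H-score columns bypass the formula but
pass the same `[0, 200]` validation, so cohorts scored directly by
pathologists and cohorts carrying raw fractions coexist.

Validation of cohort files is total: any malformed row (out-of-range score,
fractions not summing to 100, duplicate core identity, unknown site label)
raises a typed error naming the offending rows, never a partially loaded
table. Empty cells mean "not assessed" and are excluded from every
denominator downstream — denominators are therefore reported explicitly
everywhere (e.g. patient classifications return the evaluable-patient count
and the list of excluded patients).

## Subtype classification

Blocks are classified on two axes: AR signaling (AR, NKX3.1) and
neuroendocrine differentiation (SYP, INSM1). Within a block, each marker is
reconciled across cores by the maximum (a block's axis marker is present if
any core shows it); each axis is then summarised by the maximum of its two
markers and called positive at the same H ≥ 20 cut-off. The cross of the
two axis calls gives the four quadrants AR+/NE−, AR−/NE+, AR+/NE+, AR−/NE−.

The max-of-markers rule at the global cut-off was chosen for consistency:
one positivity convention across the whole package. `mean` aggregation is
available as an option for users mirroring assays that average markers. A
`subtype_label` column in the cohort file always takes precedence over the
derived call, so pathologist-assigned subtypes reproduce exactly. A block
whose axis has no measured marker is *indeterminate*: it is reported as
such (or raised, on request) rather than silently classified.

Classification defaults to the block level. Sites occasionally contain
phenotypically mixed blocks; keeping cores distinct in the schema and
aggregating per block keeps both levels available.

## Co-expression and patient classes

Co-expression tables cross-tabulate the binarized statuses of two markers
over analysis units (cores by default — TMA denominators far exceed patient
counts — or blocks). Units missing either marker are excluded from the
total. Percentages are rounded half-up (`round_half_up()`), at integer
precision by default with a one-decimal mode; half-up is the convention
that reproduces published contingency tables exactly, where banker's
rounding does not.

Patients are classified per marker over their metastatic sites (cores →
site by maximum): *non-expressor* if every site is below the cut-off,
*uniform-high* if every site reaches it, *heterogeneous* otherwise. A
single-unit patient is therefore never heterogeneous, and the three classes
partition the evaluable patients.

## Heterogeneity index

The central statistic is the probability that a random eligible pair of
samples is discordant at the cut-off. Eligible pairs are enumerated
exhaustively: within a tumor block (intra-tumoral) or across different
blocks of one patient (inter-tumoral). For a single group of `n` samples
with `k` positives, drawing two without replacement gives the concordance
`(C(k,2) + C(n−k,2)) / C(n,2)` — the hypergeometric identity; the exact
index is one minus that, pooled over groups.

Two pooling weightings are exposed. *Pair weighting* (default) treats every
eligible pair in the cohort as equally likely, which is the plain reading
of "sample 1000 random pairs". *Group weighting* averages per-group
discordant fractions unweighted, which protects small blocks from being
swamped by large ones; the choice is recorded in every output.

The bootstrap estimator draws `n_pairs` pairs (default 1000) with
replacement per replicate, over `n_boot` (default 1000) replicates; the
point estimate is the replicate mean, and the interval is BCa. The
resampling unit defaults to the pair — a documented simplification — with a
group (patient) option that respects the clustering of pairs sharing
samples. With `n_pairs = NULL` the resample size equals the pool's own pair
count, the canonical bootstrap; this is the right choice when the interval
must reflect the pool's sampling variability (as in the coverage
simulations below) rather than approximate the pooled index of a large
fixed population.

### BCa conventions

Bias-corrected accelerated limits are computed from first principles:

* bias constant `z0 = qnorm(P(t* < t0) + P(t* = t0)/2)` — the
  mid-probability tie convention. For continuous statistics it coincides
  with the usual strict-less count; for the heavily tied replicate
  distributions produced by small binary pair pools the strict count biases
  `z0` downward whenever replicate mass sits exactly at the observed value,
  which systematically shortens the upper limit. The mid-p form restores
  near-nominal coverage there (measured in the test suite).
* acceleration from the jackknife third-moment formula
  `a = Σd³ / (6 (Σd²)^{3/2})`, `d_i = mean(jack) − jack_i`; leave-one-out
  is over the resampling unit (pairs, or groups).
* endpoints are raw order statistics of the sorted replicates at index
  `ceiling(α_adj · B − 1e−9)`, clamped to `[1, B]`; the epsilon guards
  against floating-point noise at exact grid points.
* degeneracies are flagged, not raised: an all-identical replicate set
  collapses to its point mass, and an observed statistic outside the
  replicate range (infinite `z0`) falls back to plain percentile limits;
  both set the `degenerate` flag carried into every output.

Every stochastic operation takes a seed, records it in its result, and
restores the caller's RNG state, so any reported estimate is reproducible
from its own metadata.

## Association models

Site contrasts come from `H ~ site + (1 | patient)` fitted by REML
(`lme4`), with Wald z confidence limits and two-sided normal p-values and
no degrees-of-freedom correction — the estimate/CI/p surface of standard
epidemiological reporting. Vertebral bone is the default reference site.
A patient variance estimated at zero is legitimate (the fit is flagged
singular) and the estimates then coincide with ordinary least squares,
which the tests assert. Sites represented by a single sample are flagged
`wide_ci` rather than dropped.

Genomic associations regress binarized expression on a patient-level
alteration flag. The default analysis unit is the patient (any-site
positivity, plain logistic regression — one observation per patient needs
no random effect); the sample-level unit keeps every core and adds a
patient random intercept via `glmer`, reducing exactly to `glm` when every
patient has one sample. Complete separation (an empty 2×2 cell) is flagged
with the unstable estimate attached, and `glmer` convergence warnings are
captured into the result rather than printed and lost. Transcript tables
are dichotomized at FPKM ≥ 1 by default (configurable); 1 FPKM is the
customary "detectably expressed" floor for bulk RNA-seq.

No multiple-testing adjustment is applied to reported p-values; the p <
0.05 convention is annotation, never part of estimation.

Two caveats matter when interpreting single-gene odds ratios, and both are
visible in the synthetic cohort: alteration prevalence is strongly
subtype-dependent (e.g. RB1 loss enriched in NEPC), so unadjusted ORs fold
subtype effects into the gene effect; and when patient-level positivity is
nearly deterministic given subtype, the conditional (random-intercept)
model is weakly identified — its variance estimate can blow up and the
Wald SE becomes untrustworthy, which is why the convergence warnings are
part of the result object.

## Synthetic cohort generator

`generate_cohort()` emulates the structure the estimators assume, with
full ground truth (`CohortTruth`): per-block true subtype, per-sample
positivity probability, realized scores, configured site shifts and
genomic log-odds.

* **Shape.** 52 patients; zero-truncated Poisson sites per patient with
  mean 372/52; one block per site; 1–4 cores per block with probabilities
  `(0.33, 0.38, 0.22, 0.07)` — expected totals ≈ 372 sites and ≈ 753
  samples.
* **Subtypes.** A dominant subtype per patient
  (adenocarcinoma 0.55, NEPC 0.18, amphicrine 0.12, double-negative 0.15)
  with per-block switching probability 0.03, so mixed-subtype patients are
  a minority, as in real rapid-autopsy series.
* **Marker values.** Per subtype × marker, a two-component mixture:
  negative (point mass at 0 plus a scaled Beta on `[0, 20)`) or positive
  (point mass at 200 plus `20 + 180·Beta`). Positivity probability is the
  mixture weight, so genomic log-odds effects act *exactly* on
  `P(H ≥ 20)`. Default location parameters put simulated medians near the
  published subtype medians (TROP2 ≈ 200 in AR+/NE− and ≈ 0 in AR−/NE+,
  DLL3 ≈ 90 and CEACAM5 ≈ 60 in AR−/NE+, PSMA ≈ 120 in AR+/NE− and ≈ 12 in
  AR−/NE−); dispersions and mixture weights are the package's own
  calibration, fixed once.
* **Correlation.** A patient-level Gaussian effect on the positivity
  log-odds (sd 2) makes positivity cluster within patients — without it,
  independent block draws produce inter-tumoral discordance far above
  anything observed in real cohorts. A patient-level level shift (sd 10
  H-score units) and core-level noise (sd 8) perturb the score *within*
  its category: negatives stay in `[0, 19]`, positives in `[20, 200]`,
  point masses at 0 and 200 are stable readings, and emitted H-scores are
  integers, as scored on slides. Category changes arise only from the
  mixture itself and from a per-core independent redraw probability
  (`core_flip = 0.05`), the intra-tumoral discordance source.
* **Site and genomic effects.** Additive site shifts on the positive
  interior (defaults anchored to published contrasts: TROP2 liver −17 /
  lung −40, DLL3 liver +11 / lung +14, CEACAM5 prostate +19) and
  patient-level alteration flags with subtype-dependent prevalence and
  configured log-odds effects on positivity (directions anchored to the
  published associations; magnitudes kept moderate, |log OR| ≈ 0.7–1.4).

What the generator does *not* emulate: spatial structure within a slide,
assay batch effects, pre-analytic degradation of bone specimens, missing
markers, and transcript-protein discordance. Because level shifts cannot
cross the positivity threshold and point masses are held fixed, realized
mean H-score contrasts on the default cohort are attenuated relative to
the nominal site-shift parameters — the recovery simulations therefore use
a dedicated all-interior configuration where the linear model is exact.
Passing tests on synthetic cohorts demonstrate estimator correctness under
this generative model, not the biological fidelity of any particular
default.

## Simulation checks and problem sizes

The suite runs entirely from code-built fixtures; sizes were chosen so the
whole suite completes in about a minute:

* worked-example tables (contingency percentages, patient classes, subtype
  sensitivity) are reproduced exactly from fixtures matching the published
  joint counts;
* bootstrap-vs-exact agreement: 20 seeded cohorts, `n_pairs = n_boot =
  1000`, agreement within 3 Monte-Carlo standard errors;
* BCa coverage: 500 pools of 30 samples (15 two-core blocks, each pair
  independently discordant with probability 0.25), canonical resample
  size, 95% intervals covering the true 0.25 in well over 90% of pools;
* parameter recovery: 200 simulations each for the liver shift (−20,
  patient sd 10) and the genomic odds ratio (4, 100 patients), with the
  true value inside the model's own 95% CI in ≥ 90% of runs.

The pool structure of the coverage check uses independent pairs because the
estimator resamples pairs; pools dominated by pairs sharing samples would
test the (documented) limitation of pair resampling rather than the
interval machinery. The `resample_unit = "group"` option exists precisely
for such clustered pools.

## Known limitations

* The pair-resampling bootstrap understates uncertainty when many pairs
  share samples; group resampling is available but the default favours the
  plain reading of pair sampling.
* CIs on very small pools inherit bootstrap discreteness; degenerate pools
  (no discordant pair) honestly return `[0, 0]` with a flag.
* Unadjusted single-gene odds ratios conflate genotype with subtype (see
  above); a subtype-adjusted model is deliberately out of scope of the
  reported surface.
* The CEACAM5-style differing denominators seen in real cohorts (patients
  evaluable for some markers only) are handled by explicit exclusion
  bookkeeping; the package cannot reconstruct denominators a source did
  not report consistently.
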