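---
title: "Methods: methylation-based stratification of glioma immunosuppressive state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-based stratification of glioma immunosuppressive state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`edisonr` stratifies glioma cases by a binary immune-evasion flag derived
from immune-composition scores, then learns that flag from CpG methylation
β values. This vignette is the package's own account of the model, the
choices that were genuinely open, and what the synthetic validation does and
does not establish.

## The labelling model

Three per-sample scores summarise the immunosuppressive arm of the tumour
microenvironment: expression of *CD163* (the canonical M2
tumour-associated-macrophage surface marker), an M2-macrophage signature
score, and a Treg signature score. The two signature scores are treated as
upstream inputs — in practice they come from bulk deconvolution tools; the
package does not reimplement deconvolution and accepts one score per
channel.

`preprocess_scores()` log-transforms the raw *CD163* expression channel
(a pseudocount, default 1, is added only when exact zeros are present;
negative input is an error) and standardizes every channel to zero mean and
unit variance with the *population*-SD convention (divisor *n*). The
centre/scale/pseudocount per channel are stored in the result's
`"transform"` attribute so new samples can be projected onto the reference
scale without re-estimation; a zero-variance channel is a hard error, since
it cannot be standardized.

`compute_quartiles()` estimates the per-channel first quartile with the
linear-interpolation convention (`stats::quantile` type 7), pinned in code
and documentation so that stored thresholds are portable. At least four
samples are required.

`assign_edison()` flags a case positive when the number of channels
*strictly below* their first-quartile threshold satisfies the rule. Ties at
the threshold count as not-below, making the flag invariant under any
strictly increasing transform applied jointly to a channel and its
threshold. Two rules exist because the procedure's verbal descriptions are
ambiguous between "more than two" (all three) and "at least two" of the
three channels. The default is `at_least_two`; under independent continuous
scores it flags 3(¼)²(¾) + (¼)³ = 15.625% of cases, whereas the all-three
rule yields 1.6%, far below any plausibly useful positive rate. Both rules
are selectable and the choice is recorded with the result.

Whether quartiles should be computed on the pooled cohort or per grade is
not determined by the procedure's description; the package computes them
jointly on the supplied reference cohort (the conservative reading —
thresholds then mean the same thing for every case) and leaves per-cohort
thresholds to the caller, who can simply call `compute_quartiles()` per
subset.

## The synthetic cohort generator

`simulate_cohort()` draws, in order: grade (binomial, default GBM fraction
47/573); a latent binary immune state (*evading* vs *suppressed*) with
grade-dependent prevalence; three immune scores from an equicorrelated
multivariate normal (correlation `score_correlation`, default 0.3) whose
mean is shifted by `-score_effect_size` (default 3 SD) in evading samples;
expression, where the three marker rows are noisy monotone transforms of
the scores and bystander genes are negatively coupled to the mean β of
their annotated probes; the β matrix, from per-probe Beta distributions
parameterised by (mean, precision) so β ∈ [0, 1] holds by construction
rather than by clipping (precision default 30; baseline probe means are
drawn bimodally, as array β values are); and exponential survival times for
two endpoints with independent exponential censoring (default 40%
censored). The suppressed state multiplies the overall-survival hazard by
`state_hazard_ratio` (default 1/0.55), so flag-positive (evading) cases
have a generative hazard ratio of 0.55; the progression endpoint uses a
1.6× baseline hazard and state ratio 1/0.57. Informative probes (default
50 of 2000) differ in mean β between states by `effect_size_beta`
(default 0.15, direction random per probe); configurations that would push
a Beta mean outside (0, 1) are rejected at construction.

**Latent prevalence.** The default grade-conditional probabilities of the
evading state are 0.23 (LGG) and 0.09 (GBM). These preserve the direction
and rough odds of grade enrichment seen in real cohorts, but are
deliberately *not* set to the observed flag-positive rates (~54% of LGG):
a fixed first-quartile at-least-two rule can flag at most 25% of a cohort
(15.6% under channel independence), so a latent prevalence near 50% would
make the latent state unrecoverable by the flag — the analytic agreement
ceiling is about 0.74 — and the generator would no longer emulate a setting
in which the label means what it claims to mean. With prevalence ~0.22 and
a 3-SD score shift the flag recovers the latent state in ≈98–99% of
samples, which is what the recovery tests certify. Both probabilities are
configurable.

**What the generator does not emulate:** realistic probe coordinates and
linkage disequilibrium of methylation, batch and purity effects, non-PH
survival, grade-specific methylation differences beyond the latent state,
and the internal structure of deconvolution scores. Green tests therefore
certify the machinery — estimator contracts, error control, ordering
properties — not performance on patient data.

## Probe selection

`independent_filter()` ranks probes by overall β variance — a statistic
computed without labels, so downstream error control is preserved — and
keeps the top fraction (default 355,314/482,421 ≈ 0.7365, the reduction
from a full 450k array this pipeline was designed around). Ties are broken
by matrix order, deterministically.

Expert panels are plain gene lists tagged with one of five sources
(`immune_subtype`, `angiomatrix`, `ici_response`, `prognostic`, `ecm`);
`select_by_genes()` uses union semantics (a probe annotated to any panel
gene is kept), so the two standard nested sets — `ImmuneAngioICIs`
(sources 1–3) and `ImmuneAngioICIsMesECM` (1–5) — satisfy the subset
relation by construction. Panels are user-supplied content; synthetic
cohorts carry a generated panel that covers the informative probes plus
decoy genes (3× by default), so that expert selection over-covers the
signal and the data-driven step has real pruning to do.

## Shadow-feature selection

`boruta_run()` implements all-relevant selection from scratch. Per
iteration: a permuted shadow copy of *every* feature is appended, a random
forest is fitted on non-rejected real features plus all shadows, and a real
feature scores a hit when its importance exceeds the maximum shadow
importance (a 90th-percentile variant is exposed). Cumulative hit counts
are tested two-sidedly against Binomial(i, ½); extreme counts confirm or
reject a feature, survivors stay tentative.

Three numerical choices matter, all fixed by a null-calibration experiment
(random features, random labels) run before the validation suite was
frozen:

* **Importance.** Out-of-bag *scaled permutation* importance. In-sample
  impurity importance rewards chance feature–label correlations, which are
  a fixed property of the dataset and therefore beat the shadow maximum
  consistently; the Z-scored OOB measure keeps borderline features near the
  ½ hit-probability reference the binomial test assumes.
* **Forest size.** Deliberately modest (50 trees per iteration by
  default). Averaging importance over many trees makes it nearly
  deterministic, which converts weak chance correlations into systematic
  hits; per-iteration noise is part of the error control, not a defect.
* **Multiplicity.** Bonferroni over the full feature family *and* the
  sequential looks, `(α/2)/(m · max_iterations)`: the test is applied after
  every iteration, and a correction that ignored the repeated looks (or
  used the shrinking set of undecided features as its denominator)
  confirms early chance streaks. The full shadow pool is kept for the same
  reason: fewer shadows late in a run would lower the competition
  threshold exactly when spurious hit counts have accumulated.

`boruta_consensus()` repeats the run over the training partitions of a
repeated stratified cross-validation scheme (default 10 folds × 100
repeats, scalable; a full-data restart mode is also provided) and confirms
a feature overall when it is confirmed in at least `consensus_fraction` of
runs (default 0.5; 0 gives the union, 1 the intersection). Tentative
features never enter the final set — the conservative reading of
"all-relevant". Everything is deterministic given the seed.

## Classifiers and evaluation

One stratified 80/20 split (`make_split()`) is shared by every probe-set
dataset so that per-sample predictions are comparable across models.
Hyperparameters are tuned by grid-search cross-validation *inside the
training split only*, selecting on mean CV MCC; the winning configuration
is refit on the full training set and its per-fold metrics provide the 95%
confidence intervals. How such intervals should be computed is not
standardised; the package uses the t-interval over fold metrics and labels
it as a convention.

The random forest is `ranger`; the multilayer perceptron is written in
plain matrix algebra (no multi-hidden-layer network implementation exists
in the dependency set): ReLU hidden layers (default 128–128), sigmoid
output, binary cross-entropy with L2 penalty 1e-4, Adam (step 1e-3),
minibatches of 32, inputs standardized on training statistics, early
stopping on a 15% validation fraction of the training data with patience
20, all initialisation and shuffling seed-controlled.

Metric conventions: MCC returns 0 when any marginal of the confusion
matrix is empty (and equals the Pearson correlation of the binary vectors
whenever that is defined — a property the tests check exhaustively); AUC is
the Mann–Whitney rank statistic with ties counted ½, verified against
exhaustive pair counting; the McNemar comparison uses the
continuity-corrected χ² = (|b−c|−1)²/(b+c) when at least 25 discordant
pairs exist and the exact two-sided binomial test otherwise, with p = 1
when there is no discordance.

## Survival machinery

Kaplan–Meier, log-rank and the univariate Cox model are delegated to the
`survival` package behind the module interface; tests pin their behaviour
to hand-computed product-limit values. Cox uses Efron tie handling
(continuous synthetic times make ties rare regardless). Monotone partial
likelihood — complete separation of events between groups — is reported as
a distinct error (`cox_monotone_error`) rather than a silently huge
estimate; the detection combines the fitter's warning with bounds on the
coefficient (|β| > 15) and its standard error. Probe–gene correlation uses
Pearson r with t-distribution p-values, Benjamini–Hochberg adjustment
across all tested pairs, and reports zero-variance vectors as missing with
a note, never as r = 0. The progression endpoint is called PFI throughout,
with PFS accepted as an alias.

## Problem sizes used by the validation suite

The tests and `scripts/acceptance.R` run at sizes chosen so the whole
suite completes in minutes on one CPU while each check retains power: the
analytic null-rate check at n = 10⁵ (three standard errors); flag recovery
at n = 2000; planted-signal and null shadow-feature runs at n = 200 with
51/50 features, 20 runs each; the selected-vs-all-probes ordering on
cohorts of 500 samples × 5000 probes (50 informative), 20 replicates in
the tests and 5 in the acceptance script; hazard-ratio recovery over 100
(tests) or 50 (script) replicates at n = 1000; and an end-to-end pipeline
demonstration at the default cohort size of 573. These are the package's
validation conditions, not estimates of performance on any patient cohort.

## Known limitations

* The flag is a thresholding heuristic; its quartile cut points are
  cohort-relative, so transferring thresholds between cohorts requires the
  stored transform and threshold objects and a comparable score scale.
* Shadow-feature selection inherits random-forest biases (e.g. towards
  features with more distinct values); β values are homogeneous in scale,
  which mitigates but does not remove this.
* The MLP is a minimal, dependency-free implementation: no dropout, batch
  normalisation, or learning-rate schedules.
* The generator's survival model is exponential/proportional-hazards by
  construction, so Cox recovery tests cannot detect PH violations.
* Regional (island/shore/shelf/open-sea) sub-models reuse the generic
  modelling path; the package does not claim region-specific biology
  beyond what a supplied manifest encodes.
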