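---
title: "Methods: robust reactive-peptide detection from peptide microarray scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust reactive-peptide detection from peptide microarray scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Peptide microarrays probe an antibody repertoire against thousands of
peptides at once: a serum or plasma sample is incubated on a slide
carrying printed peptide spots, bound antibodies are detected with a
dye-coupled secondary antibody, and the slide is scanned. The question
per peptide is binary — did the sample react with it? — but the raw
spot intensities are dominated by nuisance structure:

* **printing effects** — each block of spots is deposited by one print
  needle, and needles differ systematically; slides printed in
  different batches differ again;
* **incubation effects** — reagent flow across the slide creates
  smooth spatial gradients along rows and columns, plus irregular
  per-row/per-column deviations;
* **spot artifacts** — dust, smears, and malformed spots corrupt
  individual measurements;
* **secondary-antibody binders** — some peptides bind the labelled
  detection antibody directly, producing strong signals that have
  nothing to do with the sample.

`pepscreen` implements a multi-stage pipeline that removes each of
these in turn and then calls reactive peptides probabilistically.

## Slide geometry and controls

The default slide (`array_layout()`) carries 3 identical subarrays
stacked vertically; each subarray holds 16 blocks in a 4×4 grid, each
block printed by one needle and holding 20×20 spots — 19 200 spots per
slide, 240 global rows × 80 global columns. Every peptide appears once
per subarray at the same within-subarray position, giving triplicates
per slide. `resolve_address()` maps GPR block/row/column addresses to
subarray, needle, global row and global column.

10% of spots are dedicated controls (`default_layout()`): 5% positive
(react with any sample), 2.5% secondary-antibody (react with the
detection antibody alone), 1% negative, and 1.5% process controls — 13
distinct control peptides, placed so every block carries repeats of
every class and every block row and column contains controls. Within a
block, controls are laid out as a connected chain (two per row, the
second column shared with the next row) so that row and column
contrasts remain estimable rather than splitting into disconnected
aliased groups; the class cycle is rotated per needle so no class is
confined to the same rows everywhere.

## Normalization

Raw intensities are variance-stabilized with a binary log,
`log2_transform()`, with values below a floor (default 1) mapped to 0.
On the log scale the model is additive:

```
log2(intensity) = peptide + array + subarray + needle + row + column + noise
```

`fit_effects_model()` fits this by ordinary least squares **on the
control spots only** — controls are the only peptides whose identity
repeats densely across all positions, so their intensities separate
position effects from peptide effects. All factors are categorical;
the sequential ANOVA table (peptide first, then the position factors)
is retained on the model object. With the default design the
degrees-of-freedom pattern is Peptide 12, Subarray 2, Needle 15, Row
234, Column 76 (some contrasts are aliased by the layout and are
recorded in `aliased_terms`).

`correct_effects()` subtracts the estimated position effects — each
factor's per-level estimates centered to sum to zero, so the overall
intensity scale is preserved — from **every** spot, experimental and
control. `variance_reduction()` reports the fraction of control
variance (after removing peptide identity) explained by the position
factors; on realistic synthetic slides this is ~0.8.

Two caveats are deliberate. First, individual per-level row/column
effects are weakly identified on a chain design; only the combined
per-spot adjustment and the fitted values are identifiable, and the
tests assert exactly those. Second, the model is fitted per slide:
print-batch structure is handled by analysing each slide against its
own controls, not by pooling.

## Spot quality control

Replicate disagreement defines "unreliable". `band_label()` regresses
each subarray's log intensities on each other subarray's (per peptide)
and flags spots falling outside the 95% **prediction band** — the band
for a new observation, `fit ± t·s·√(1 + 1/n + (x−x̄)²/Sxx)`. (The
narrower mean-response confidence band is available but flags far more
spots at realistic n.) These labels are training data, not final
judgements: `train_reliability_classifier()` fits a random forest (500
trees, `mtry = floor(√p)`, classes balanced by downsampling via
`balance_classes()`) on per-spot quantification features — intensity
statistics from the incubation scan plus geometry/uniformity features
from a label-free scatterlight scan joined via `join_scans()`. The
forest generalizes the replicate-agreement signal to features that do
not require replicates, and is applied to new slides with
`predict_reliability()`.

`aggregate_replicates()` collapses triplicates to one value per
peptide: unreliable replicates are dropped, the rest averaged weighted
by their predicted reliability probability; peptides with no reliable
replicate are excluded rather than imputed.

## Secondary-binder exclusion and signal calling

Both decisions use the same machinery: a two-component Gaussian
mixture fitted by expectation–maximization (`em_fit()`) to the
per-peptide aggregated, normalized intensities of one slide. The
E-step is computed with log densities; the M-step applies a variance
floor (1e-6); iteration stops at a relative log-likelihood change
below 1e-8 or 1000 iterations; components are relabeled at exit so
component 1 (noise) has the lower mean. Initialization comes from
controls (`init_from_controls()`), with mixing weights (0.9, 0.1).

Given the fit, `exceedance_prob()` computes for each peptide the
probability that a draw from the noise component is at least as large
as its value; a peptide is called when that probability is **strictly
below** α (default 0.05), equivalently when its value exceeds the
upper-α quantile of the noise component. α is the explicit
sensitivity/specificity dial. `posterior_fdr()` offers an alternative,
off-by-default criterion based on the posterior probability of noise
membership; it leans harder on the normality of the signal component.

* On an **empty slide** (incubated with diluent only) any reactivity
  is secondary binding; `detect_secondary_binders()` initializes from
  negative and secondary-antibody controls and excludes every
  experimental peptide called reactive there from the sample slides of
  the same print batch. Under the α = 0.05 rule about 5% of truly
  clean peptides are excluded along with the binders; that is the
  designed false-exclusion rate, not a defect.
* On a **sample slide**, `call_signals()` initializes from negative
  and positive controls, removes the batch's exclusion set before
  fitting, and emits a call table with per-peptide exceedance
  probabilities, calls, and exclusion reasons.

## Evaluation

`evaluate_calls()` scores calls against a truth assignment
(sensitivity, specificity, accuracy). Excluded peptides are omitted
from the denominators by default; `count_excluded_as_negative = TRUE`
counts them as non-reactive calls instead. `bootstrap_ci()` attaches
percentile confidence intervals by resampling peptides within each
truth class and re-calling against the fixed fitted cutoff;
deterministic under its seed. `run_pipeline()` orchestrates the whole
workflow from a manifest of GPR files (or a YAML config) and
`write_bundle()` emits TSV/JSON outputs.

## The synthetic generator

`generate_experiment()` produces the six-slide study design — two
print batches, each with one empty, one low-spike and one high-spike
slide — with full ground truth (peptide reactivity, planted secondary
binders, per-spot artifact flags, and the injected effect values).
Intensities follow the additive log2 model above, exponentiated to the
raw scale (so raw-scale noise grows with the mean, as in real scans).
Needle and subarray effects are drawn per print batch; the array
offset and row/column gradients per slide; batch 2 gets an extra
offset and a higher artifact rate. Artifact spots receive large
intensity perturbations with correlated aberrant scatterlight features
(spot diameter, pixel noise, circularity).

Default effect scales are calibrated arithmetically from the magnitude
relationships the pipeline is designed for: per-level row/column
deviations of sd ≈ 0.4 on the log2 scale (large enough that
uncorrected analysis visibly suffers), spike effects of 3 (high) and
1.3 (low) log2 units against an aggregated-value sd of ≈ 0.55, which
predicts near-perfect sensitivity at high and ~0.8 at low
concentration — the regime the method is meant to resolve. 222
spike-target and 171 expected-nonreactive truth peptides give 666 and
513 spots per slide. Everything is deterministic given `seed`, and the
generator restores the caller's RNG state.

## Numerical choices

* GPR/ATF round trips are bit-exact: numbers are written with `%.17g`.
* EM: relative tolerance 1e-8, variance floor 1e-6, max 1000
  iterations.
* The least-squares fit is validated in the tests against a
  minimum-norm pseudo-inverse solve of the normal equations.
* All stochastic steps (class balancing, forest training, bootstrap,
  generation) take explicit seeds and restore the global RNG state.

## Sizes and limitations

A full slide is 19 200 spots (5 760 experimental peptides ×3); the
effects model fits on 1 920 controls; mixtures fit on ~5 800
aggregated values. The full test suite, including full-size end-to-end
runs, completes in well under a minute.

Limitations: the noise component is assumed Gaussian after
normalization (the exceedance rule uses only its upper tail, which
softens this); per-level row/column estimates are not individually
interpretable; the classifier is only as good as the band labels it is
trained on and should be retrained when scanner or chemistry changes;
and calls are per-slide — combining slides beyond the built-in
replicate structure is left to the caller.
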