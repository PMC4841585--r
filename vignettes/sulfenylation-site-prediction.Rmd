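---
title: "Predicting cysteine S-sulfenylation from sequence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cysteine S-sulfenylation from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

S-sulfenylation oxidizes a cysteine thiol to sulfenic acid (–SOH). It is
reversible, redox-regulatory, and — like most cysteine modifications —
site-specific: within one protein some cysteines are modified and others
never are. `sohsite` treats site prediction as binary classification of
*peptide windows*: each cysteine is represented by the 10 residues on
either side of it,

$$P \;=\; R_{-10}\,R_{-9}\cdots R_{-1}\,\mathrm{C}\,R_{+1}\cdots R_{+10},$$

a 21-residue string in which flanks running past a protein terminus are
padded with the dummy residue `X`. The window half-width of 10 reflects
the short tryptic peptides from which sulfenylome sites are mapped
(average flank lengths of roughly 6 ± 4.6 residues): a wider window would
be mostly padding, a narrower one would discard observed sequence.

Positives are windows around experimentally modified cysteines; negatives
are **all other cysteine windows from the same proteins**. This negative
definition matters: it forces the classifier to separate modified from
unmodified cysteines within comparable sequence context, rather than
separating cysteine-containing proteins from random ones.

## Window encodings

The central cysteine is constant and carries no information, so only the
20 flanking positions are encoded.

* **binary** — each flank position becomes a 21-long one-hot indicator
  (residues ordered `A..Y` with `X` last), concatenated to 420 dimensions.
  Lossless and assumption-free; `decode_binary()` inverts it exactly.
* **psaap** — position-specific amino-acid propensity. `fit_psaap()`
  tabulates, over the *positive training windows only*, the frequency of
  every residue at every flank position (a 21 × 20 column-stochastic
  matrix); a window is then encoded as the 20 looked-up frequencies of its
  own residues. The matrix is a plain positional frequency without
  smoothing or background correction — the cited propensity construction
  leaves room for both, and rather than guess we keep the estimator
  elementary; windows resembling the modified class receive uniformly
  high values.
* **aaindex** — each flank residue contributes 14 physicochemical scales
  (hydrophobicity, solvent accessibility, polarity, polarizability,
  accessible surface area, pK-N, pK-C, melting point, molecular weight,
  optical rotation, net charge, entropy of formation, heat capacity,
  absolute entropy), 280 dimensions in all. The bundled table
  (`inst/extdata/aa_properties.tsv`) records the AAindex accession of each
  scale and can be replaced via `aa_properties(path = ...)`.

Raw AAindex scales differ in magnitude by four orders (molecular weight
~100 vs net charge ~0.01); an RBF kernel on raw values would effectively
see only the largest scale. Each scale is therefore min–max normalized to
[0, 1] over the 20 amino acids by default (`normalize_properties()`,
idempotent; a constant scale is rejected as an error). `X` is pinned to 0
on every scale — padding carries no physicochemical signal — so fully
padded flanks encode to exact zeros.

PSAAP fitting is the one encoder step that learns from data, and it is
deliberately confined to training positives: inside cross-validation the
matrix is refitted within each training fold, so a held-out window can
never influence its own features.

## Classifier and class imbalance

Classification uses a support vector machine with RBF kernel
(γ = 0.005, cost C = 1). γ is small relative to the feature counts, which
keeps the kernel nearly linear and resists overfitting the modest positive
class; C is not stated by the benchmark protocol we follow and stays at
the library default, exposed as a parameter. Decision values come from
libsvm (via `e1071`), which is deterministic given the training set.

Probabilities are obtained by Platt scaling: a logistic sigmoid
$p = 1/(1+e^{a f + b})$ fitted by `glm` to the training labels against the
training decision values. We fit the sigmoid ourselves rather than using
libsvm's built-in calibration because the latter randomizes an internal
cross-validation from a seed outside R's RNG, breaking reproducibility;
the sigmoid is monotone in the decision value, so ranking metrics (AUC)
are unaffected by this choice, and calibration fitted in-sample is
slightly optimistic but serves only the fixed 0.5 call cutoff. A window
is called modified when its probability **strictly exceeds** the cutoff —
a probability exactly at the cutoff is a negative call.

Curated sulfenylome data are imbalanced roughly 7:1 against positives,
and an SVM trained on the raw data maximizes accuracy by under-calling
the positive class. Both training and evaluation therefore balance by
subsampling negatives:

* `soh_cv(k = 10, repeats = 20)` — each repeat draws a fresh balanced
  subsample (all positives + an equal-size uniform draw of negatives),
  splits it into `k` stratified folds, trains on `k − 1` folds and scores
  the held-out fold; the pooled held-out scores of a repeat give one AUC
  and one confusion matrix at the cutoff, and repeats are summarized as
  mean ± sample SD. Stratified round-robin fold assignment guarantees
  both classes in every fold whenever `k` does not exceed the per-class
  count (enforced), so no fold ever degenerates to a single class.
  AUCs are averaged per repeat (not pooled into one curve), matching the
  mean-±-SD reporting of a scalar metric.
* `soh_fit(n_models = 20)` — the served model is an ensemble over
  balanced subsamples whose probabilities are averaged. The benchmark
  protocol trains on balanced data but does not state a final deployed
  model; an averaged ensemble is the natural continuation of the repeated
  subsampling and avoids privileging one arbitrary draw.

All subsampling, fold assignment and generation is driven by explicit
integer seeds; identical seeds give identical subsample indices, folds
and (the solver being deterministic) identical predictions.

## Metrics

From the confusion counts, sensitivity SN = TP/(TP+FN), specificity
SP = TN/(TN+FP), accuracy ACC = (TP+TN)/n and the Matthews correlation

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

When a denominator factor is zero (e.g. a constant classifier) MCC is
undefined; `compute_metrics()` returns 0 with a warning, the standard
convention that keeps summaries finite. Internally all rates are
fractions; percentages appear only in printed reports.

The ROC sweep groups tied scores into a single step and integrates by
trapezoid, which makes the AUC exactly the pairwise concordance
probability P(score⁺ > score⁻) + ½P(tie) — the property the test suite
verifies against a brute-force pairwise oracle on random score sets.

## Redundancy filtering

Homologous peptides shared between folds inflate apparent performance, so
`redundancy_filter()` removes windows with ≥ 40% pairwise identity. Two
semantics decisions, both fixed and documented rather than configurable:

* Identity is positional identity over the aligned 21-mers with the full
  window length as denominator, `X` matching `X` included. Windows are
  equal-length and centered by construction, so no alignment is needed.
  A consequence worth knowing: two windows whose flanks are mostly
  padding can exceed the threshold on shared `X` positions alone, so
  heavily padded windows are filtered aggressively.
* Removal is a greedy representative-keeping scan in input order (as
  CD-HIT does): the earlier window of an offending pair survives.
  Removing *both* members would annihilate whole similarity clusters,
  which is incompatible with a filtered benchmark retaining most of its
  peptides. The filter is idempotent, and positives and negatives are
  filtered jointly over the combined dataset.

## Positional composition and enrichment

`composition_matrix()` gives per-position residue frequencies with
padding excluded from the denominator, so short flanks do not dilute the
composition of residues actually observed. `two_sample_enrichment()`
contrasts the two classes per (position, residue) with a two-proportion
z-test (chi-squared without continuity correction), falling back to
Fisher's exact test when any expected cell count is below 5. Results are
reported at a fixed significance level (default p < 0.01) without
multiple-testing correction — the convention of two-sample logo displays,
whose outputs this table is designed to feed. Directions are antisymmetric
under swapping the classes, and the result set at a stricter α is always
a subset of the result set at a looser one.

## The synthetic benchmark

`generate_benchmark()` exists so that every stage — extraction, encoding,
training, evaluation, enrichment — is testable without downloads. It
emits one protein per site: a single central cysteine with flanks drawn
residue-by-residue from a background distribution, and a site table
labelling each cysteine. Its defaults are fixed study conditions, not
tuning knobs:

* **Motif**: one enrichment rule per position — K at −6, −5, −2, +7, +8;
  R at −4; E at −3, +1, +3, +4, +5 — each firing with probability 0.35.
  This mirrors the positional K/R/E enrichment (and its spread across
  both flanks) reported for sulfenylated peptides, reduced to one residue
  per position so that every rule can keep the full 0.35 rate while the
  per-position probabilities remain a valid distribution. Multiple rules
  may share a position if their probabilities sum to at most 1.
* **Background**: uniform over the 19 non-cysteine residues (≈ 0.053
  each). Excluding cysteine keeps exactly one labelled cysteine per
  protein, so class counts are exact and re-extraction recovers precisely
  the planted windows.
* **Flank lengths**: rounded normals, upstream 5.8 ± 4.7 and downstream
  7.0 ± 4.5 truncated to [0, 10], emulating the short-peptide reality of
  sulfenylome data and exercising the `X`-padding paths. Positive flanks
  are additionally extended to cover every planted position, so a rule
  with probability 1 is guaranteed to appear.

`null_benchmark()` uses the same machinery with no rules: labels are
independent of sequence, so the true AUC of any classifier is 0.5 — the
calibration control.

What the generator does **not** emulate: residue–residue correlations,
compositional bias of real proteomes, homology structure (every synthetic
window is independent), and multi-cysteine proteins. Passing the
synthetic tests therefore demonstrates that the pipeline recovers planted
positional signal and is honest under the null — not that real
sulfenylomes are predicted at any particular accuracy. Reproducing
published benchmark performance requires the curated peptide table, which
cannot be redistributed with the package; when that table is supplied
(see `tests/testthat/test-acceptance.R`) the full 20 × 10-fold protocol
runs against it.

## Problem sizes and numerical details

The test suite and `scripts/acceptance.R` use planted benchmarks of
500 + 500 sites (signal recovery, independent split), 200 + 200 (null
calibration), and 10-fold cross-validation with 3–5 repeats; these sizes
give binomial standard errors of ~0.02 on frequencies and keep the full
suite in the low minutes on a single core, while the package defaults
(`repeats = 20`) match the benchmark protocol for real data. Other
numerical conventions: PSAAP columns sum to 1 within 1e-12 of exactness
(plain ratio arithmetic); window extraction is 1-based in every
user-facing table; non-standard FASTA residues (B, Z, J, U, O, `*`) map
to `X` with a warning rather than an error; an empty sequence is an
error while a cysteine-free protein legitimately yields zero windows.

## Known limitations

* Calibration is fitted in-sample, so predicted probabilities are
  slightly overconfident near the extremes; rankings are unaffected.
* The PSAAP encoder compresses a window to 20 looked-up frequencies and
  discards residue identity; it is the weakest encoder on data whose
  signal is physicochemical rather than positional.
* The redundancy filter's padding-counts-as-identity rule over-removes
  windows near protein termini; with very short peptides, filter before
  interpreting class counts.
* No hyperparameter search is provided (γ and C are fixed defaults), and
  no alternative classifiers; the package implements one protocol well
  rather than a model zoo.
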