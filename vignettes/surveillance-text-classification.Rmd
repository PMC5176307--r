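---
title: "Methods: text-based case classification for ASD surveillance"
author: "asdsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-based case classification for ASD surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

ASD surveillance systems of the ADDM type classify a child as meeting the
surveillance case definition by expert clinician review of every abstracted
developmental evaluation. `asdsurv` models that decision as a supervised
text-classification problem: the unit of analysis is the *child*, the
predictor is the bag of stemmed 1–3-grams in the concatenation of the
child's evaluations, and the label is the clinician's final classification.
A random forest supplies both the classifier and — through out-of-bag (OOB)
permutation importance — the feature selector.

The method makes three substantive assumptions:

* **Bag-of-words sufficiency.** Word and phrase occurrence patterns carry
  enough of the clinical description to reproduce the case decision; word
  order beyond the 3-gram window, negation and document structure are
  ignored.
* **Stability across years.** A model trained on one surveillance year
  transfers to the next: the vocabulary, document frequencies and document
  count are *frozen* at training and reused verbatim to vectorize later
  years. Drift in how clinicians describe symptoms degrades this silently,
  which is why the evaluation layer is part of the package.
* **Label fidelity.** The clinician classification is the target, not some
  latent "true ASD status"; the algorithm cannot exceed clinician
  inter-rater agreement, and its honest training estimate is the OOB one.

## Pipeline parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `ngramMin`–`ngramMax` | 1–3 | phrase window; 3 captures "poor eye contact"-style symptoms |
| `minDfFraction` | 0.03 | a term must occur in ≥3% of child documents (ceiling rule; 35 of 1162) to enter the vocabulary |
| `stemmer` | `"porter"` | Porter suffix stripping; recorded in the artifact so train/predict always match |
| `nTreesSelection` | 10000 | selection forest; importance estimates stabilize with many trees |
| `nTreesFinal` | 3000 | reduced-feature refits and final model |
| `kCandidates`, `kStep` | 175, 5 | candidate pool from the importance ranking and the nested-subset grid |
| `tolerance` | 0.005 | absolute OOB-accuracy slack for preferring a smaller subset |
| cutoff | non-case fraction | vote-share threshold, e.g. 561/1162 = 0.483; calibrates predicted prevalence to training prevalence |

Forest hyperparameters other than tree count are the `randomForest`
classification defaults (`mtry = sqrt(p)`, unlimited depth), recorded into
the model artifact's manifest for provenance.

### Feature selection rule

The reduction from the 175-term candidate pool to the final model is
implemented as an explicit, auditable rule: refit forests on the nested
top-k subsets (k = 5, 10, …, 175), measure each refit's OOB accuracy, and
keep the smallest k within `tolerance` of the best. The k-versus-accuracy
trace is stored in the classifier (`@selectionTrace`) and in the artifact.
The number of terms selected on synthetic corpora is whatever the rule
yields — typically a few dozen — and is not pinned to any particular value.

## Text processing details

* **Aggregation order.** Evaluations are concatenated in ascending age at
  evaluation, ties broken by source (alphabetical) then input order. The
  bag-of-words features are order-invariant; the fixed order exists so that
  artifacts are byte-reproducible.
* **Separator.** A single space joins evaluations — any whitespace is
  equivalent under tokenization; one canonical choice avoids accidental
  token merging, and n-grams *can* span adjacent evaluations of the same
  child (they never span children).
* **Tokenization.** Digits and punctuation (hyphens and apostrophes
  included) are deleted and the text split on runs of non-letters. No
  stop-word removal is applied: the document-frequency filter and IDF
  weighting already down-weight ubiquitous words (`log2(N/df) = 0` at
  `df = N`).
* **Stemmer dialect.** The Porter (1980) algorithm is implemented in the
  package (no stemmer dependency is used), with two standard amendments
  that match the Snowball English behavior on short words: step 1c turns a
  final *y* into *i* only when preceded by a consonant (so *play*, *played*
  and *playing* share one stem), and step 5a keeps a final *e* after a stem
  of fewer than three letters (so *eye* stays whole). The test suite pins
  ~85 published word/stem pairs.
* **Document frequency** is computed on child-level aggregated documents,
  not individual evaluations, because the child is the classification unit.
* **TF-IDF variant.** Relative term frequency times `log2(N/df)`. The
  relative (length-normalized) term frequency is the classic text-mining
  choice; it also removes the gross document-length signal, leaving the
  length contrast between cases and non-cases to enter only through content
  terms. The variant is isolated in `applyTfidf()` so a raw-count variant
  is a one-line swap.

## Numerical and degenerate-input choices

* `minDfCount()` is `ceiling(n × fraction)` with a `round(·, 9)` guard so
  exact products (e.g. 100 × 0.03) are not pushed up by floating-point
  noise.
* A score exactly equal to the cutoff is classified **case** (`score ≥
  cutoff`).
* AUC uses the rank (Mann–Whitney) form with ties credited ½ — forest vote
  shares live on a 1/ntree grid, so ties are real.
* Children whose documents contain no in-vocabulary term are scored on an
  all-zero feature row and flagged (`oov = TRUE`), never dropped: a
  surveillance system must emit a decision for every child.
* Metrics with empty denominators (e.g. PPV with no positive calls) are
  `NA`, never fabricated; percentages are reported to 1 decimal and kappa
  to 2, with unrounded values retained under `$raw`.
* Prevalence CIs use the Poisson log-normal approximation
  (`rate × exp(±1.96/√cases)`), the conventional surveillance interval;
  proportions in the concordance profile use Wilson intervals. Both are
  labelled in the output.
* One master seed fans out deterministically to per-stage seeds
  (selection forest, each top-k refit, final forest), so every stochastic
  output is reproducible and stages can be re-run independently.

## The synthetic-corpus generator

Real surveillance records are confidential, so validation runs on
generated corpora with known truth. `synthConfig()` defaults emulate the
published structure of an ADDM surveillance year:

* case fraction 601/1162 ≈ 0.517; `addmLikePair()` reproduces the
  2008-like (1162 children / 601 cases) and 2010-like (1450 / 754) cohorts
  by exact allocation;
* evaluations per child: shifted negative binomial targeting medians 7
  (case) and 4 (non-case); age at first evaluation: log-normal targeting
  medians 40 and 53 months; school/health source mix per class;
* metadata flags (prior ASD diagnosis/special-education classification,
  sex, race/ethnicity, IQ ≤ 70, secondary review) drawn at per-class rates
  in the neighbourhood of the published concordance table;
* text: per-evaluation multinomial token draws over a Zipf-profiled noise
  vocabulary (class-independent) plus planted discriminative terms whose
  per-token usage logit rises by `effectLogOdds` (default 2.0) in cases,
  with a per-child Normal(0, 0.5) random effect shared across the child's
  evaluations (within-child correlation). Multi-word planted phrases are
  emitted as contiguous runs so the n-gram extractor can rediscover them.

`baselineProb = 0.003` per token makes a planted term present in roughly a
third of non-case documents and nearly all case documents at the default
effect — strong but not separable-by-one-term signal. These values were
fixed once as a realistic regime; they are conditions, not tuning knobs.

**What the generator does not emulate:** clinical prose, negation,
misspellings, abbreviation conventions, correlated symptom clusters, or
real ADDM vocabulary. Passing tests demonstrate that the machinery —
vectorization, selection, calibration, evaluation — is correct under a
known generative model; they do not forecast operating characteristics on
real records.

### Why the null configuration equalizes document length

The default generator reproduces the real cohort's contrast in evaluations
per child (medians 7 vs 4). That contrast is itself textual signal: longer
composite documents differ in n-gram diversity, so a forest can separate
the classes even with zero planted effect. A "no-signal" experiment that
leaves it in place is therefore not null. `nullSynthConfig()` zeroes the
planted effects *and* equalizes the per-class evaluation-count
distributions; metadata contrasts are retained because they never enter
the features. Under it, held-out AUC sits at chance and kappa at zero
(within the tolerances asserted in the test suite).

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` scale the forests down —
300-tree selection forests and 300–500-tree refits, corpora of 250–500
children with 300–500 noise terms for the property checks, and the full
1162/1450 ADDM-sized pair with a ~2,200-term vocabulary for the end-to-end
run. These sizes were chosen so the whole validation cycle completes in a
few minutes while leaving every statistical property (planted-term
recovery, OOB honesty, null safety, sweep monotonicity) comfortably
testable; the 10,000/3,000-tree defaults remain the recommended production
configuration. With the default generator richness the vocabulary lands in
the low thousands; pushing `nNoise` and `tokensMu` up recovers the
10⁴-term scale of a real surveillance year at proportional cost.

## Known limitations

* Transfer across surveillance *sites* (rather than years) is untested and
  likely optimistic under the frozen-vocabulary assumption.
* Whether to refit IDF statistics on a new year is a genuine open choice;
  the package freezes training statistics (the conservative option for a
  deployed classifier) and isolates the decision in `buildTdm(vocabulary=)`.
* The OOB training summary reports the final refit's metrics; a selection
  effect from reusing the same data for importance ranking and subset
  choice remains (the held-out evaluation in the test suite bounds it).
* No probability calibration beyond the vote-share cutoff, no alternative
  learners, and no clinician-certainty modelling.
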