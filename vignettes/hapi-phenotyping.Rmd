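---
title: "Phenotyping hospital-acquired pressure injury from EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping hospital-acquired pressure injury from EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehapi)
```

## The problem

A hospital-acquired pressure injury (HAPI) is a pressure injury (PI) that is
new, or worsens, during a hospital stay. HAPI incidence is a core nursing
quality metric, and machine-learning work on predicting HAPI from electronic
health records (EHR) depends entirely on how stays are labeled. The trouble
is that EHR evidence for a PI is scattered across four sources of very
different reliability — timed staging assessments in the chart-event stream,
free-text clinical notes, untimed billing diagnosis codes, and procedure
codes — and these sources frequently disagree. Published case definitions
for the same ICU database differ along eight concrete decision dimensions
and produce materially different cohorts.

`ehapi` implements this labeling problem as a configurable rule engine.
Four built-in policies cover the published definitions:

| policy | deceased excluded (D1) | min age (D2) | admission window (D3) | min stage (D4) | DTI/unstageable (D5) | note keywords (D6) | deterioration only (D7) | ICD-9 (D8) |
|---|---|---|---|---|---|---|---|---|
| `ehapi`    | yes | 15 | 24 h | 2 | yes | yes | yes | no |
| `cantrip`  | no  | 15 | 48 h | 1 | yes | yes | no  | no |
| `cramer`   | no  | 18 | 24 h | 2 | no  | no  | no  | no |
| `sotoodeh` | no  | 18 | —    | — | —   | yes | no  | yes |

All four share the common inclusion criteria: at least one clinical note,
discharge after admission, age at or above the policy minimum, and no PI
documented on admission.

## Stage semantics

Numeric PI stages run 1–4; two further categories carry no visible numeric
stage: deep tissue injury (DTI) and unstageable wounds (obscured by slough
or eschar). The engine encodes them asymmetrically:

* at admission DTI counts as stage **4** and unstageable as **0**;
* at discharge DTI counts as stage **3** and unstageable as **5**.

The discharge value of 5 lets an unstageable wound qualify as
hospital-acquired regardless of what was documented at admission, while the
DTI pair (4 at admission, 3 at discharge) makes a DTI that is still a DTI at
discharge read as an improvement, which the deterioration rule (D7) then
excludes. The admission stage is the **maximum** encoded value charted
within the admission window — the "worst documented on admission" reading,
consistent with present-on-admission coding practice; in the absence of any
admission staging the stage is 0. The discharge stage is the encoded value
of the **last** event beyond the window whose encoded value is at least the
policy's minimum stage (read as "at or above" the minimum: the published
dimension table lists 2 as the minimum stage for the strictest policies, so
a strict "above 2" would contradict it). Events tied on the latest timestamp
resolve to the maximum encoded value, which is deterministic and
order-independent.

Two further reading decisions were genuinely open:

* **Admission DTI/unstageable and the admission screen.** The "no PI
  documented on admission" criterion is triggered only by numeric stages
  1–4 inside the window. Admission DTI and unstageable events instead flow
  into the encoding logic above. Otherwise the admission encodings (DTI → 4,
  unstageable → 0) could never matter, and an unstageable wound on admission
  that is later staged — which regulatory guidance explicitly treats as
  reportable — could never become a case.
* **Policies without a staging timeline** (`sotoodeh`) screen admission PIs
  with the 24-hour note-mention check only; diagnosis codes are untimed and
  cannot be placed at admission.

## Notes, keywords and negation

The keyword route scans notes for a configurable phrase list ("pressure
ulcer", "decubitus", "bedsore", ...) with word-boundary, longest-phrase-first
matching. A mention is discarded as negated when a negation trigger ("no",
"denies", "no evidence of", ...) occurs within five tokens before it in the
same sentence, or when a structured dismissal pattern ("bedsore: none")
follows it. This is deliberately a simple window-based negation detector;
contextual or uncertainty-aware negation is out of scope, and the default
phrase and trigger lists are an overridable emulation of site-specific
inventories, not a canonical lexicon — counts on any real export will depend
on the lists supplied.

Notes carrying a date but no time are placed at midnight and flagged. They
are scanned for the admission screen (conservative: an admission-day mention
counts against the stay) but never establish an event time, since an
hour-resolution comparison against the 24/48-hour thresholds is not
meaningful for them.

## Event timestamps and the leakage-safe benchmark

Comparing definitions by training classifiers on their labels requires that
the features contain no trace of the label. Each stay therefore gets an
**event timestamp**, and only notes strictly before it ("notes of interest")
are concatenated into the stay's document:

* stays with timed PI evidence take the earliest staging event or
  non-negated keyword mention later than 24 h after admission;
* the remaining stays receive a **duration-matched** timestamp: the
  note-duration of evidence stays (event time minus earliest note) is fitted
  by maximum likelihood over candidate families (exponential, gamma,
  lognormal, Weibull); one duration is sampled per control, sampled and true
  durations are paired by rank, and each control's offset is the minimum of
  the paired values, capped at discharge. This prevents the classifier from
  learning "long note history = control".

Family selection scores all candidates on the same 20 equal-probability
bins (empirical quantile edges) with a Pearson chi-square of observed
versus model-implied counts, **penalized by `qchisq(0.95, 1)` per estimated
parameter**. The penalty matters: the two-parameter families nest the
exponential, so their raw chi-square is almost always marginally smaller on
exponential data; requiring a significant improvement per extra parameter
makes selection consistent while still recovering gamma or lognormal truths
when they hold. With fewer than 20 usable durations, or degenerate
durations, the model falls back to bootstrap resampling of the observed
durations and is flagged.

Documents are checked against the no-leakage invariant (no non-negated
lexicon phrase may survive; any residual occurrence is scrubbed and
counted), and stays with no notes of interest are excluded from the
experiments.

Test sets share all consensus cases (case under every definition) and any
manually annotated disagreement stays, and differ only in the random
subsample of consensus controls; the default control subsample targets a 7%
test prevalence. Each definition trains on its own eligible stays outside
the test set with its own labels. One model is trained per test partition —
pooling a single training set and excluding the union of all ten test pools
would starve it of controls. Hyperparameters are selected by 5-fold
stratified cross-validation (maximizing AUPRC) on the first partition and
reused. Two classifiers are provided: gradient boosting (xgboost) on
TF-IDF vectors (smoothed inverse document frequency
`log((1+n)/(1+df)) + 1`, L2-normalized rows, 5000-term vocabulary fitted on
training documents only) and a small sequential neural network (learned
word embeddings over 800-token sequences, global max pooling with padding
masked, one ReLU dense layer, sigmoid output, full-batch Adam). Reported
metrics are AUPRC and AUROC per test set with means and SDs, and a paired
one-sided t test compares the best definition against each other one;
degenerate difference vectors are flagged rather than erroring (identical
vectors report p = 0.5, constant nonzero differences p = 0).

## The synthetic cohort generator

`generate_cohort()` emits MIMIC-III-schema tables with exact per-stay,
per-definition ground-truth bookkeeping. Its defaults are the package's
study conditions:

* 7% of stays get a qualifying PI trajectory (new stage-2+ after 24 h,
  unstageable-then-staged, or admission-DTI-that-worsens), and 6% a
  non-qualifying distractor (stage-1-only, improving DTI, PI on admission) —
  each decision dimension has at least one discriminating pattern;
* PI onset lags the 24-hour admission window by an exponential with mean
  60 h; stay durations are lognormal with a median of eight days (ICU-range
  hospital stays); ages are truncated-normal (mean 64, SD 16) with a small
  rate of ~300-year obfuscated dates of birth that exercise the loader's
  age clamp (cap 90);
* in-hospital death 8%; per-source emission probabilities
  chart 0.95 / note 0.55 / ICD-9 0.40 / procedure 0.08 make chart events the
  dominant indicator and procedure codes rare, echoing the incongruence
  phenomena the congruence analytics are built for;
* 8% of stays get a negated or structured-dismissal mention, 5% of filler
  notes are date-only, 1% of stays have no notes.

Notes are templated sentences around a filler vocabulary — sufficient for
the lexicon/negation logic and bag-of-words separability, with no ambition
of realistic clinical language. An optional **signal token** can be planted
in pre-onset notes of case stays to make cohorts separable by construction
for classifier sanity checks; it is off by default. Identical parameters
and seed reproduce byte-identical tables.

Because the generator computes ground truth from the evidence it actually
emitted, the package engine can be validated against it exactly; an
additional, deliberately naive transcription of the definition semantics
(token-based scanning, hard-coded constants, nested loops) lives in the
test suite and must agree with the engine stay-for-stay on randomly
generated cohorts. Passing these tests shows the engine implements the
stated semantics — it does not show that the default lexicons or item maps
match any particular hospital's documentation habits, and template notes
cannot surface the harder negation or abbreviation phenomena of real
clinical text.

## Problem sizes and numerical choices

The test suite validates the engine against the naive labeler on 50 cohorts
of 500 stays, checks classifier separability on an 800-stay separable
cohort over 10 test partitions, and the acceptance script labels a
2000-stay cohort and benchmarks an 800-stay one — sizes at which every
property of interest is already exercised. Timestamps are parsed as naive
wall-clock datetimes (the schema has no timezone); "within 24 hours" is a
closed comparison (`<=`) and "later than 24 hours" strict (`>`), identically
at 48 h. Empty stores, empty chart-event tables, stays with zero notes,
single-class training labels, and degenerate t-test inputs all have defined
behavior rather than errors where the contract allows it.

## Worked example

```{r example, eval = FALSE}
sim <- generate_cohort(generator_params(n_stays = 500, seed = 7))
store <- as_cohort_store(sim)

labels <- lapply(builtin_definitions(), function(cfg) label_cohort(store, cfg))
sapply(labels, function(l) label_summary(l)$prevalence_pct)

ov <- definition_overlap(labels)
ov$consensus        # stays every definition calls a case
head(ov$combinations)

si <- source_indications(store)
upset_counts(si)$totals
```

## Known limitations

* One PI per stay: concurrent injuries at different anatomical sites are
  not matched between admission and discharge.
* The negation detector is a fixed-window trigger scan; hedged or distant
  negations are missed.
* Diagnosis codes are untimed, so the ICD-9 route can neither be placed at
  admission nor contribute an event timestamp.
* Synthetic notes are templates; no conclusion about real-text performance
  follows from the bundled cohorts.
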