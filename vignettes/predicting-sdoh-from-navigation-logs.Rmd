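---
title: "Predicting social determinants of health from navigation tracking logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting social determinants of health from navigation tracking logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navsdoh)
library(dplyr)
```

## The problem

Patient navigators help people overcome barriers to care — transportation,
housing, language access, insurance, fear. Each interaction (an *encounter*)
is written into a tracking log: demographic attributes per patient, plus a
longitudinal record of encounters with free-text navigator notes and coded
social determinants of health (SDoHs) from a 22-category taxonomy. Because
many barriers take several encounters to surface, a model that predicts a
patient's likely SDoHs from the data already on file can point navigators at
barriers worth screening for early.

`navsdoh` implements two such modelling pipelines end to end:

1. **A single-label comparison grid.** Six data-preparation strategies turn
   encounter histories into labelled instances, navigator notes become
   latent Dirichlet allocation (LDA) topic probabilities, and five standard
   classifiers are compared under 10-fold cross-validation across a grid of
   topic counts — 130 configurations under the defaults
   (4 note strategies × 6 topic counts × 5 algorithms + 2
   demographics-only strategies × 5 algorithms).
2. **A multi-label network on harmonized two-site data.** Records from a
   second site with an incompatible codebook are consolidated, each
   patient's three most frequent barriers become a 0/1 target matrix, the
   feature set is augmented with encounter-intensity bins and travel
   information, and a small 9-layer 1D convolutional network predicts all
   classes simultaneously through sigmoid outputs.

Real navigation logs are protected study records, so the package ships a
synthetic two-site generator with known ground truth; every stage is
validated against it.

## The preparation strategies

Encounters are heavily dominated by the language/interpreter barrier in
language-discordant cohorts, and a single encounter may carry several codes
or none. The six strategies handle this as follows. When an encounter lists
several codes, its single most *salient* code is the one with the highest
corpus-wide frequency (ties break lexicographically, so the rule is
deterministic and seed-free). Encounters whose only annotation is the
wildcard `"none"` carry no predictable barrier and are excluded from
single-label instance building, as are patients left with no retained
encounters.

* **s1** – each patient is one instance. Scanning chronologically, the
  first encounter whose salient code is not language/interpreter supplies
  the label, and encounters up to *and including* it are aggregated into
  the feature bundle (numeric fields averaged, categoricals by mode, notes
  concatenated). The trigger encounter is included deliberately: its note
  presumably discusses the labelled barrier. All-language patients keep the
  language label and contribute only their first encounter, which damps the
  dominant class.
* **s2** – s1 with language-labelled instances removed.
* **s3** – each encounter is one instance (demographics repeated).
* **s4** – s3 with language-labelled instances removed.
* **s5 / s6** – the labels of s1 / s2 with all encounter-derived features
  removed (demographics only).

Because s3/s4 repeat each patient's demographics across many instances,
cross-validation folds for them are **grouped by patient** by default;
ungrouped folds would place near-duplicates of a training row in the test
set and flatter every classifier. Ungrouped folds remain available via
`run_config_cv(..., grouped = FALSE)` for comparability with pipelines that
ignore this leak.

## Notes to topic features

Navigator notes are short (a dozen tokens), so the package fits LDA by
collapsed Gibbs sampling (implemented in C++ within the package) with
symmetric priors `alpha = 1/k`, `beta = 0.1` and a 500-sweep default. The
small document prior matters: a heavy prior would swamp an 8–12 token note
and push every vector toward uniform. No "optimal k" is selected — the
design explicitly sweeps `k ∈ {5, 10, 15, 20, 25, 30}` instead, because
coherence-style selection is unreliable on very short notes.

Document vectors are computed by a deterministic fixed-point inference with
the topic–word distribution held fixed, so converting a training note
reproduces its stored vector to numerical tolerance, and inference needs no
random seed. Empty or missing notes map to the uniform vector: no
information, no bias. Within cross-validation the topic model is fitted on
the training fold only (default) to avoid leaking held-out vocabulary;
full-corpus fitting is available behind a flag
(`lda_full_corpus = TRUE`) for fidelity to pipelines that fit once up
front. The same leakage trade-off exists for imputation statistics, which
are computed on the full dataset before splitting — the traditional
pipeline order — and we flag rather than hide that choice.

## The comparison grid and confusion-row statistics

The five algorithms (multinomial logistic regression, random forest,
RBF-kernel support-vector machine, single-hidden-layer neural network,
Gaussian naive Bayes) run with their widely used default
hyper-parameters — the comparison is between data preparations, not tuned
models. Accuracy is plain multiclass accuracy averaged over 10 folds, and
held-out predictions are pooled into a confusion summary whose **rows index
the predicted class**: each row answers "of everything the model called X,
what was it really?".

Two row statistics matter. `row_composition()` gives counts and exact
percentages per true class. `grouped_confidence()` gives the cumulative
share of a row covered by its `m` most frequent true classes (always
including the predicted class): a model may be only ~79% right that a
patient's barrier is language/interpreter yet ~95% confident the truth lies
in {language, social support, fear}. These grouped classes are how
co-occurring, easily confused SDoHs are surfaced to navigators. Percentages
are returned exactly; display rounding is left to the caller, since
reported tables of this kind round inconsistently (a 21/22 row may be
printed as 96% although it is 95.45%).

## Harmonizing a second site

Site B records one SDoH per encounter as a generic/specific code pair, has
no note text, and collapses employment to three levels. Consolidation keeps
the attribute intersection, recodes values toward the richer codebook
(3-level employment expands onto the site-A occupation categories), and
maps site-B codes through an editable alias map: a specific code with a
direct correspondence uses it, otherwise its generic parent's
correspondence, otherwise `"other"`. Values in a foreign script become
`"none"`; unspecified codes fall back to `"chose not to answer"`/`"other"`
where the attribute offers them. The shipped alias map is illustrative —
the true cross-study correspondence table is not public — and is meant to
be replaced via `read_alias_map()`.

Each patient's compiled codes fill `barrier_1..3` (three most frequent;
ties by first occurrence then lexicographically), and actions fill
`intervention_1..3`. Encounter intensity is binned L/M/H/VH with fixed
thresholds `<3`, `3–15`, `16–29` (inclusive), `>29` — the fixed
reference scheme — or rederived from the cohort as
`round(mean − sd), round(mean), round(mean + sd)` via
`derive_bins()`. Boundary counts 3 and 16 fall upward (M and H) per the
wording "<3" and ">29"; 29 stays in H. Travel augmentation
(nearest hospital, distance, drive and transit minutes) sits behind a
provider interface; the package ships a CSV fixture provider and a
haversine provider over synthetic zip-code centroids, so nothing touches a
network. Missing transit times take the observed mean, matching the
numeric imputation rule elsewhere.

## The multi-label network

The network is small and fully specified, so it is implemented directly in
the package (vectorised matrix algebra, exact backpropagation, Adam):
a 1D convolution over the feature sequence (10 filters, kernel width 3,
ReLU), max-pooling (size 2, stride 2), flatten, then three
(dropout 0.25, dense) pairs of widths 3C, 2C, C with a final sigmoid — nine
layers. Sigmoid + binary cross-entropy score each class independently,
which is what multi-label prediction of up-to-three barriers requires.
Sigmoid outputs are thresholded at 0.5 (the natural operating point when
no cost asymmetry is specified); per-class correct/incorrect counts
accumulate over 10 folds, and per-class accuracy is the reported metric.

Training defaults: 100 epochs, batch 32, Adam with step size 0.003 (the
other moment parameters at their usual values). The step size is the one
departure from textbook defaults: with only tens of hidden units, 0.001
converges too slowly for features at the edge of the input sequence, whose
signal the convolution/pooling front end attenuates (an edge position
appears in one window; interior positions in three). That attenuation is a
real property of this architecture worth knowing when ordering features.

Intensity classification (predicting L/M/H/VH from demographics) uses a
support-vector classifier under the same fold scheme, and
`attribute_correlations()` reports plain Pearson correlations between every
attribute column and every SDoH indicator — identical to the point-biserial
coefficient for 0/1 pairs. Zero-variance columns yield `NA`, reported, not
dropped silently.

## The synthetic generator, and what it does not show

`generate_cohort()` draws per-patient encounter counts from a negative
binomial with mean 16.94 and SD 13.06 — realistic navigation-cohort
moments whose overdispersion the negative binomial matches. Each encounter fires each
SDoH category independently (Bernoulli), with log-odds shifted by the
patient's demographics and by the encounter's latent topic mixture;
`"none"` is emitted when nothing fires. Notes are bag-of-words samples from
the topic mixture (length ~ Poisson, mean 12) — enough structure for LDA,
no grammar. One dominant category (language/interpreter, base rate 0.45)
reproduces the heavy class imbalance such cohorts show. The default
demographic links attach one barrier to mutually exclusive levels of an
attribute (English level, occupation, income, education); overlapping links
would funnel labels onto the single globally most frequent code through the
salience rule and erase the very per-class signal the links are meant to
plant. `signal_strength` scales all links; 0 removes the signal entirely,
and 4 is the "strong injection" setting used by the recovery benchmarks.

Default cohort size is 330 patients, a realistic single-study enrolment.
Benchmarks in the test-suite use: signal recovery at n = 1000 over 5 seeds;
the planted-rule network benchmark at n = 1500 with 10 folds; generator
calibration checks at n = 2000. These sizes give stable means while keeping
a full run in minutes.

What passing these tests shows is that the machinery — strategies,
topic features, cross-validation, harmonization, the network — recovers
signal that is present and reports nothing when it is absent. It does not
show that real tracking logs carry comparable signal: real notes are
bilingual and code-switched (the synthetic ones are monolingual token
streams), real missingness is not independent across columns, and real
SDoH co-occurrence is richer than independent Bernoulli draws. Published
headline accuracies from any particular study are properties of that
study's data and are not reproducible from synthetic cohorts.

## Numerical and degenerate-input choices

* Missing sentinel: `NA`, with empty strings and common missing tokens
  normalised on parse. Imputation: numeric → mean, categorical → mode with
  lexicographic tie-break (deterministic without seeds).
* Encounter order: recorded date, ties by file order.
* Constant encounter counts make derived intensity bins degenerate
  (`sd = 0`) — an error with guidance, not a silent fallback.
* An all-missing column cannot be imputed — an error naming the column.
* A class with fewer members than folds downgrades stratified folds to
  unstratified, with a warning.
* All randomness flows from explicit integer seeds; re-running any
  function with the same inputs and seed is bit-reproducible, and every
  written artifact carries a hash of its producing configuration.
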