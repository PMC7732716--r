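---
title: "Screening medical articles for adverse drug events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening medical articles for adverse drug events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Pharmacovigilance under recall-based reporting (the regime used in Japan)
requires pharmaceutical companies to report *any* possible adverse drug
event (ADE) found in the medical literature. Manual triage of articles is
the bottleneck: a first screening decides which articles contain ADE
references at all, and a second, expert screening locates and assesses the
ADE descriptions. `adescreen` implements a two-stage automated counterpart:

1. **Document level** — classify each article as *ADE containing*
   (it has at least one ADE-suggesting sentence) or not, replacing the
   first screening.
2. **Sentence level** — inside articles, classify each sentence as
   *ADE suggesting* or not, pointing the expert at the passages to read.

A sentence is ADE suggesting when an adverse event is mentioned after a
drug prescription (criterion A) or when the author explicitly mentions a
suspicious ADE (criterion B). The document label is *derived*: an article
is ADE containing if and only if some sentence in it is ADE suggesting,
and the package enforces this invariant on every corpus it reads or
generates.

## The pipeline

### Preprocessing

Raw article text (typically OCR output) is cleaned by dropping stray
symbols (default `$` and `^`; the set is configurable because the stray
inventory is OCR-dependent) and segmented into sentences. The
segmentation rule is script-aware: split after the Japanese full stop
`。` always, and after an ASCII period only when the preceding character
is a Japanese letter, where "Japanese letter" is formalized as membership
in the Unicode blocks Hiragana (U+3040–309F), Katakana (U+30A0–30FF) or
CJK Unified Ideographs (U+4E00–9FFF). This keeps decimal numbers
(`3.5`) and Latin abbreviations intact. Delimiters stay attached to the
preceding sentence, so concatenating the output reproduces the input
exactly — a property the test suite checks on random mixed-script
strings. Newlines are treated as ordinary whitespace rather than sentence
boundaries because OCR line breaks are unreliable.

### Entity recognition

Disease and drug mentions are located by a character-level sequence
labeler over the IOB2 tag space `{B-disease, I-disease, B-drug, I-drug,
O}`. The labeler is a maximum-entropy tagger: one joint multinomial
logistic regression (ridge-penalized, fitted with `glmnet`) over a sparse
indicator template of character identities, character bigrams, and
Unicode script classes within a ±2-character window. A single joint
model over the five tags is the default because the two entity types are
trained identically and a joint model covers both with one fit; training
two separate binary taggers through the same interface is possible by
filtering the training spans. Decoding is greedy left-to-right under the
IOB2 well-formedness constraint (`I-x` only directly after `B-x`/`I-x`),
and the standalone decoder repairs orphan `I-x` tags to `B-x`, the
standard deterministic repair that keeps decoding total.

Because the evaluation questions in this package concern the
classification stages, the evaluation harness defaults to *oracle spans*
(the corpus' gold entity annotations) rather than re-extracted ones; a
trained tagger can be substituted via `evaluation_config(spans = model)`.
This separates tagger quality from classifier quality in all downstream
measurements.

### Normalization

Surface variation ("many variations on the same disease and drug names")
is resolved against two dictionaries mapping surface forms to standard
names — stand-ins for large terminologies such as the MANBYO (disease)
and HYAKUYAKU (drug) resources. The similarity between an extracted
surface `a` and a dictionary surface `b` is

> `sim(a, b) = 1 − Levenshtein(a, b) / max(|a|, |b|)`

which is bounded in [0, 1], symmetric, 1 exactly on equal strings, and
length-scale free; the max-length denominator is our choice of
normalization (the underlying edit-distance idea admits several). A
mention is replaced by the standard name of the most similar dictionary
surface provided the similarity *strictly exceeds* the threshold, default
0.3; otherwise it is left unnormalized. Ties between equally similar
surfaces go to the lexicographically smallest surface form, which makes
the result independent of dictionary file order. The candidate search is
exhaustive; at dictionary sizes where that matters, a length-difference
prefilter would be a pure optimization and must not change results.

### Features

Six sparse, interpretable feature groups; documents use the first three,
sentences all six:

| group | content |
|---|---|
| `word_tokens` | bag-of-words token counts |
| `std_name` | count per *standard* (normalized) disease/drug name |
| `sum_name` | two features: total disease mentions, total drug mentions |
| `ctx_word_tokens` | word tokens of the previous + next sentence, pooled |
| `ctx_std_name` | standard names of the neighbors |
| `ctx_sum_name` | mention totals of the neighbors |

Design points, each of which was genuinely open:

* **Vocabulary.** Tokens appearing once in the training folds are
  removed (`min_count = 1`). Vocabularies are fitted on training folds
  only and carry a hash of the texts they were fitted on; the
  cross-validation harness asserts that hash, so train/test vocabulary
  leakage is structurally impossible rather than merely avoided.
* **Tokenizer.** A pluggable function; the default splits on whitespace
  after mapping punctuation (including `。`/`、`) to spaces. A
  morphological analyzer (e.g. for Japanese, where words are unspaced)
  can be plugged in through the same contract; the synthetic corpora are
  whitespace-tokenizable by design so the pipeline needs no
  language-specific binary.
* **Counts vs indicators.** All bag features are term counts by default
  ("sum of frequency" semantics); binary indicators are switchable via
  `evaluation_config(binary = TRUE)`.
* **`sum_name` vs `std_name`.** `sum_name` counts *every* recognized
  mention, normalized or not, while `std_name` counts only normalized
  ones. This reading keeps the two groups non-redundant: the first
  measures how entity-dense a text is, the second which entities it is
  about.
* **Context.** Previous and next sentence are pooled into one context
  group (summed counts) rather than direction-tagged, and a missing
  neighbor at an article boundary contributes nothing (no sentinel
  feature). Context features carry distinct names (`ctx_*`) so the
  classifier weighs in-sentence and context occurrences separately.

### Classification

Both classifiers are L2-regularized logistic regressions with uniform
class weights, decision threshold 0.5 on the probability scale, fitted
with `glmnet` at `alpha = 0`, `lambda = 1/n`, unstandardized features and
an unpenalized intercept. That is exactly the objective of a
default-parameter scikit-learn `LogisticRegression` (`C = 1`, L2), which
we verified numerically: on identical design matrices the two give the
same test-fold F1 to four decimals. Recording the objective this
precisely is what makes the behavior portable across implementations.

The sentence classifier is trained only on sentences of ADE-containing
articles — label proportions are otherwise unworkable because negative
articles contribute no positive sentences — and evaluated on *every*
sentence of the test folds ("flat" evaluation). The deployed
`screen()` pipeline instead gates sentence classification on the
document decision (`mode = "pipeline"`); both behaviors exist because
deployment and evaluation legitimately differ here, and on articles the
document stage passes, the two modes produce identical sentence
probabilities.

Interpretability is a first-class output: `coef()` returns every feature
with its group and weight sorted by magnitude, the export round-trips
into a working classifier, and models serialize to JSON.

### Evaluation harness

* **Folds.** Stratified k-fold at the document level: per class, shuffled
  round-robin assignment with a rotating class offset, so fold sizes and
  per-fold positive counts are as equal as possible (within one
  document). A class with fewer than `k` members yields a warning, not an
  error — small corpora are still splittable, some folds simply lack that
  class.
* **Metrics.** `prf()` uses the convention that precision, recall and F1
  are 0 when their denominator is 0. Precision–recall curves have one
  point per distinct score (predict positive at `score >= t`). Cohen's
  κ is computed from the marginals and is reported as undefined (an
  explicit error) when chance agreement equals 1.
* **Spread.** The SD over folds uses the population formula (divide by
  `k`), recorded in the output (`sd_formula`), because with k = 5 the
  choice visibly matters.
* **Ablation.** Each named feature group is removed in turn and the
  model re-cross-validated with identical folds and seed; ΔF1 is
  reported against the all-groups baseline. The pseudo-group `"dummy"`
  (one all-zero feature) exists to demonstrate that removing a vacuous
  group reproduces the baseline bit for bit.
* **Learning curves.** Training folds are subsampled (stratified,
  seeded per fold) at each fraction; fraction 1.0 reproduces
  `cross_validate()` exactly. On the sentence task with all six groups
  and small fractions, training F1 reaches 1.0 while validation F1 stays
  materially lower — the overfitting regime expected when context
  features triple the dimensionality of an already small problem.

## What the synthetic generator emulates — and what it does not

The generator exists so every stage is testable without any private
corpus. Its defaults encode the corpus structure the package targets:

* 58.9 % of documents ADE containing (`positive_rate = 0.589`);
* one *contiguous* run of ADE-suggesting sentences per positive document,
  length ~ round(Normal(3.9, 2.7)) clamped to ≥ 1 — contiguity mirrors
  annotation practice where the ADE-suggesting designation spans
  consecutive sentences, and each member sentence is labeled
  individually (no run object is stored);
* a background of non-ADE sentences per article,
  count ~ round(Normal(48.2, 72.1)) clamped to ≥ 1. Clamping (rather
  than resampling) is our recorded choice of how to truncate; it shifts
  the realized mean upward somewhat, which we accept since any
  nonnegative-integer distribution with roughly these moments serves;
* criterion A vs B mixed at 3.5 : 0.4 within runs; criterion-A sentences
  place a drug mention before a disease mention, criterion-B sentences an
  explicit statement with a disease mention;
* entity mentions drawn as dictionary surface variants, further perturbed
  per character at `variant_noise`;
* cue phrases (two-token phrases from a closed cue vocabulary) in
  ADE-suggesting sentences with probability `cue_strength` — the tunable
  lexical signal;
* background sentences of *positive* documents additionally carry single
  cue-style tokens at rate `bg_style_rate * cue_strength` (default
  0.3 × cue_strength). This emulates case-report phrasing that pervades
  ADE-containing articles beyond the annotated run — the same phenomenon
  that makes general statements read like actual cases and is a known
  source of sentence-level false positives. It also makes the document
  signal length-proportional, which is what lets a bag-of-words
  classifier on raw counts succeed on documents whose lengths vary by
  two orders of magnitude;
* general-statement distractors: background sentences mention diseases
  and drugs at `bg_disease_rate`/`bg_drug_rate` (default 0.2) without
  being ADE suggesting;
* text is a whitespace-tokenizable pseudo-language over closed syllable
  inventories with *disjoint initial letters* per word class (disease,
  drug, filler, cue), so entity surfaces can never collide with filler —
  this is what makes tagger recovery expected by construction. An
  optional Japanese mode transliterates every syllable to katakana and
  exercises the script-aware segmentation path end to end.

The generator deliberately does **not** emulate: linguistically real
Japanese; per-block character counts (matching both sentence counts and
character counts would over-constrain the pseudo-language); correlated
discourse structure beyond the single contiguous run; OCR noise in the
default corpus (available separately as `perturb_ocr()`, which
substitutes/deletes characters at a given rate and remaps or drops gold
spans). Consequently, passing signal-recovery tests here demonstrates
that the pipeline's machinery is correct and leak-free — not that any
particular F1 will be attained on real articles, where vocabulary is
open, entities are not lexically disjoint from context, and annotation
is noisy.

A null configuration (`cue_strength = 0`, `equalize_classes = TRUE`)
generates positives and negatives from the same distribution; document
CV F1 then collapses to the always-positive baseline `2p/(1+p)`, which
the test suite checks — a guard against accidental label leakage through
the generator itself.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open everywhere; a span's surface
  must equal its text slice, enforced at construction.
* Normalization threshold comparison is strict (`>`), so a best
  similarity exactly at the threshold leaves the mention unnormalized.
* Empty dictionaries normalize nothing and are not an error.
* `fit_logistic` refuses single-class training sets; learning-curve
  folds whose subsample is single-class are skipped with a warning.
* Same config + seed reproduce corpora, dictionaries, folds, fits and
  predictions byte for byte; all randomness flows through explicit seeds
  (`withr::with_seed`), and glmnet fits are deterministic.

## Problem sizes used in the shipped tests

Module tests run on compact corpora (tens of documents with shortened
backgrounds, mean 10 sentences) chosen to exercise every code path
quickly; the signal-recovery and ablation checks use 150-document
corpora; the headline signal-recovery check and `scripts/acceptance.R`
use the full study-shaped configuration (500 documents, background mean
48.2/SD 72.1, `cue_strength = 0.9`, `variant_noise = 0.05`, 30 canonical
names per entity type, fivefold CV). These sizes are the package's
choices for a thorough-but-quick default run; all of them are plain
function arguments, and nothing in the code depends on them.

## Known limitations

* The context window is the adjacent sentence pair; ADEs described
  across wider spans need paragraph-level models or sequence labeling
  over sentences, which this package intentionally does not include.
* The tagger's feature template is a minimal standard one (the original
  disease-extractor's template is unpublished); it is recorded in the
  model metadata, and oracle-span mode keeps downstream results
  independent of it.
* Dictionaries map surfaces to a standard *string* only; linking to
  coding systems (MedDRA, ICD) is out of scope.
* Word embeddings and neural classifiers are deliberately excluded: the
  design premise is small annotated corpora, language-independent
  features, and in-house maintainability, with interpretability via
  exported coefficients.
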