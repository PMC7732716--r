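# adescreen

Two-stage screening of medical articles for adverse drug events (ADEs),
for pharmacovigilance teams working under recall-based reporting — the
regime (used in Japan) where *any* possible ADE in the literature must be
reported, so the bottleneck is manual triage. The package automates the
first screening (which articles contain ADE references at all?) and
supports the second (which sentences inside them suggest the ADE?).

## What it implements

An article is **ADE containing** iff at least one of its sentences is
**ADE suggesting** (an adverse event mentioned after a drug prescription,
or an explicitly stated suspicious ADE). The pipeline:

1. **Preprocess** — strip stray OCR symbols; segment sentences at `。`,
   and at `.` only after a Japanese letter (hiragana/katakana/CJK).
2. **Entity recognition** — character-level IOB2 tagging of disease and
   drug mentions with a maximum-entropy sequence tagger (character
   n-gram and script-class features, constrained decoding).
3. **Normalization** — map each mention to a dictionary standard name by
   edit-distance similarity `1 − Lev(a,b)/max(|a|,|b|)`, accepting the
   best match only when similarity exceeds 0.3.
4. **Classification** — two L2-regularized logistic regressions
   (the objective of scikit-learn's `LogisticRegression` defaults:
   ridge at `λ = 1/n`) over six interpretable sparse feature groups:
   word-token counts, standard-name counts, mention totals, and their
   previous/next-sentence context versions (documents use the first
   three). Sentence models train only on sentences of ADE-containing
   articles.
5. **Evaluation** — stratified fivefold CV with training-fold-only
   vocabularies (leakage is asserted away via corpus hashes), F1,
   precision–recall curves, feature-group ablation (ΔF1), learning
   curves, and Cohen's κ for annotation agreement.

A seeded synthetic-corpus generator reproduces the statistical shape of
an annotated case-report corpus (58.9 % positive documents, contiguous
ADE runs of mean 3.9 sentences against backgrounds of mean 48.2, entity
surface variants, tunable cue-phrase signal), so the whole pipeline is
testable without any private data. See the methods vignette
(`vignettes/ade-screening.Rmd`) for the full design rationale.

## Worked example

```r
library(adescreen)

cfg   <- generator_config(n_docs = 120, seed = 7)
dicts <- generate_dictionaries(cfg)
corp  <- generate_corpus(cfg, dicts)
corp
#> <ade_corpus> 120 articles (70 ADE containing), 7180 sentences

cross_validate(corp, task = "document", dictionaries = dicts, k = 5, seed = 7)
#> <ade_cv> document task, 5 folds (seed 7): mean F1 0.931 (SD 0.0555)
```

The mean F1 is the average over the five test folds (here the per-fold
values are 1.00, 0.92, 0.96, 0.93, 0.83); the SD uses the population
formula over the folds. Training and screening by hand:

```r
norm  <- normalize_corpus(corp, dicts)
vocab <- fit_vocabulary(unlist(lapply(norm, function(a)
           vapply(a$sentences, function(s) s$text, character(1)))))
doc_model  <- train_document_model(norm, vocab, seed = 7)
sent_model <- train_sentence_model(norm, vocab, seed = 7)

res <- screen(norm[4:6], doc_model, sent_model, mode = "pipeline")
res$documents
#>     doc_id        prob pred
#> 1 doc00004 0.865103431    1
#> 2 doc00005 0.014226997    0
#> 3 doc00006 0.005256847    0
subset(res$sentences, pred == 1)
#>     doc_id sent_id      prob pred
#> 2 doc00004       1 0.7902777    1
```

In pipeline mode only the article predicted ADE containing
(`doc00004`, probability 0.87) gets sentence predictions; its sentence 1
is flagged ADE suggesting with probability 0.79 — that is the sentence a
reviewer would read first. The classifier is fully inspectable:

```r
head(coef(doc_model), 5)
#>       feature       group    weight
#> 1 sum|disease    sum_name 0.6240962
#> 2   wt|yuwewo word_tokens 0.5469300
#> 3   wt|wayuyo word_tokens 0.5432183
#> 4   wt|yawayu word_tokens 0.5009360
#> 5    sum|drug    sum_name 0.4271250
```

The strongest weights sit on the disease-mention total and on cue-word
tokens — exactly the signal the generator plants. Ablation quantifies
group contributions as ΔF1 against the all-groups baseline:

```r
ablation(corp, "document", groups = c("word_tokens", "sum_name"),
         dictionaries = dicts, k = 5, seed = 7)
#>         group f1_without     delta_f1
#> 1 word_tokens  0.6229545 -0.307586846
#> 2    sum_name  0.9364672  0.005925926
```

Removing word tokens costs 0.31 F1; removing the two mention-total
features changes almost nothing here.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ade-screen.R` (subcommands `simulate`, `validate`,
`train`, `screen`, `evaluate`, `coefficients`, `kappa`).

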