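# Evaluation harness: stratified k-fold CV, precision/recall/F1,
# precision-recall curves, feature-group ablation, learning curves, and
# Cohen's kappa for annotation agreement.
#
# Conventions: the positive class is "ADE containing" / "ADE suggesting";
# precision, recall and F1 are 0 when their denominator is 0; the SD over
# folds uses the population formula (divide by k); every report echoes the
# fold seed so the random splits are reproducible.

#' Precision, recall and F1 from confusion counts
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric: `precision`, `recall`, `f1` (harmonic mean);
#'   each is 0 when its denominator is 0.
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

binary_f1 <- function(pred, truth) {
  prf(sum(pred == 1L & truth == 1L),
      sum(pred == 1L & truth == 0L),
      sum(pred == 0L & truth == 1L))[["f1"]]
}

#' Precision-recall curve
#'
#' One operating point per distinct score: at threshold `t`, instances with
#' `score >= t` are predicted positive. Thresholds are strictly increasing
#' and recall is non-increasing along the curve.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (both classes must be present).
#' @return An `ade_pr_curve`: data frame with `threshold`, `precision`,
#'   `recall`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    ade_stop("pr_curve: both classes must be present")
  }
  thresholds <- sort(unique(scores))
  npos <- sum(labels == 1L)
  pts <- t(vapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    c(precision = if (sum(pred)) tp / sum(pred) else 0,
      recall = tp / npos)
  }, c(precision = 0, recall = 0)))
  structure(
    data.frame(threshold = thresholds, precision = pts[, "precision"],
               recall = pts[, "recall"]),
    class = c("ade_pr_curve", "data.frame"))
}

#' Cohen's kappa for two binary annotations
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with chance
#' agreement computed from the two raters' marginals.
#'
#' @param labels_a,labels_b Equal-length binary label vectors.
#' @return Kappa in `[-1, 1]`; an error is signalled when chance agreement
#'   is 1 (both raters constant and equal), where kappa is undefined.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.integer(labels_a); b <- as.integer(labels_b)
  if (length(a) == 0L || length(a) != length(b)) {
    ade_stop("cohen_kappa: labels must be equal-length and non-empty")
  }
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a == 1L) * mean(b == 1L) + mean(a == 0L) * mean(b == 0L)
  if (pe >= 1) ade_stop("cohen_kappa: undefined (chance agreement is 1)")
  (po - pe) / (1 - pe)
}

#' Stratified k-fold assignment of articles
#'
#' Random splits with the label proportion kept: per class, shuffled
#' round-robin assignment with a rotating class offset, so fold sizes and
#' per-fold positive counts are as equal as possible (within one document).
#'
#' @param articles An `ade_corpus`, or an integer vector of document
#'   labels.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold indices in `1..k`, one per article
#'   (named by `doc_id` when a corpus was given). A class with fewer than
#'   `k` members triggers a warning (some folds then lack that class).
#' @export
stratified_kfold <- function(articles, k = 5L, seed = 1L) {
  labels <- if (inherits(articles, "ade_corpus")) doc_labels(articles)
            else as.integer(articles)
  stopifnot(k >= 2L)
  if (length(unique(labels)) < 2L) {
    ade_stop("stratified_kfold: both classes must be present")
  }
  if (length(labels) < k) {
    ade_stop("stratified_kfold: need at least k = %d articles", k)
  }
  if (any(table(labels) < k)) {
    warning(sprintf(
      "stratified_kfold: a class has fewer than k = %d members; some folds will lack it",
      k), call. = FALSE)
  }
  folds <- integer(length(labels))
  offset <- 0L
  withr::with_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  if (inherits(articles, "ade_corpus")) {
    names(folds) <- vapply(articles, function(a) a$doc_id, character(1))
  }
  folds
}

#' Evaluation configuration
#'
#' @param min_count Vocabulary exclusion threshold (see
#'   [fit_vocabulary()]).
#' @param threshold Normalization similarity threshold.
#' @param tokenizer See [tokenize_words()].
#' @param groups Feature groups; `NULL` means the task default (three
#'   document groups / six sentence groups).
#' @param binary Binary indicators instead of counts.
#' @param spans `"gold"` to use gold entity spans, or a trained
#'   `ade_ner_model` to re-extract spans before normalization.
#' @return A config list for [cross_validate()] and friends.
#' @export
evaluation_config <- function(min_count = 1L, threshold = 0.3,
                              tokenizer = tokenize_words, groups = NULL,
                              binary = FALSE, spans = "gold") {
  list(min_count = min_count, threshold = threshold, tokenizer = tokenizer,
       groups = groups, binary = binary, spans = spans)
}

prepare_eval_corpus <- function(corpus, dictionaries, config) {
  corpus <- predict_corpus_spans(config$spans %||% "gold", corpus)
  if (!is.null(dictionaries)) {
    corpus <- normalize_corpus(corpus, dictionaries,
                               config$threshold %||% 0.3)
  }
  corpus
}

# Core CV engine shared by cross_validate / ablation / learning_curve.
# Returns per-fold validation F1, training F1, and per-fold (scores, labels)
# for PR curves. `fraction` subsamples training documents (stratified by
# document label, seeded per fold); folds with a single-class subsample are
# skipped with a warning (F1 = NA).
run_cv <- function(design, folds, task, groups, config, seed,
                   fraction = 1.0) {
  k <- max(folds)
  min_count <- config$min_count %||% 1L
  tokenizer <- config$tokenizer %||% tokenize_words
  fold_f1 <- train_f1 <- rep(NA_real_, k)
  fold_scores <- vector("list", k)
  for (f in seq_len(k)) {
    train_docs <- which(folds != f)
    test_docs <- which(folds == f)
    if (fraction < 1) {
      train_docs <- withr::with_seed(seed * 1000L + f, {
        keep <- unlist(lapply(split(train_docs,
                                    design$doc_labels[train_docs]),
                              function(idx) {
          m <- max(1L, round(fraction * length(idx)))
          sample(idx, m)
        }), use.names = FALSE)
        sort(keep)
      })
    }
    train_sent <- which(design$sent_doc %in% train_docs)
    vocab_texts <- design$texts[train_sent]
    vocab <- fit_vocabulary(vocab_texts, tokenizer, min_count)
    # leakage guard: the vocabulary must have been fitted on exactly the
    # training-fold sentence texts
    stopifnot(identical(vocab$fitted_on, ade_hash(vocab_texts)))
    X <- assemble_design(design,
                         if (task == "document") "document" else "sentence",
                         vocab, groups, binary = isTRUE(config$binary))
    if (task == "document") {
      tr <- train_docs; te <- test_docs
      y <- design$doc_labels
    } else {
      tr <- which(design$sent_doc %in% train_docs &
                    design$doc_labels[design$sent_doc] == 1L)
      te <- which(design$sent_doc %in% test_docs)
      y <- design$sent_labels
    }
    fit <- tryCatch(fit_logistic(X[tr, , drop = FALSE], y[tr], seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("fold %d skipped: %s", f, conditionMessage(fit)),
              call. = FALSE)
      next
    }
    model <- list(weights = fit$weights, intercept = fit$intercept)
    tr_scores <- classifier_scores(model, X[tr, , drop = FALSE])
    te_scores <- classifier_scores(model, X[te, , drop = FALSE])
    train_f1[f] <- binary_f1(as.integer(tr_scores >= 0.5), y[tr])
    fold_f1[f] <- binary_f1(as.integer(te_scores >= 0.5), y[te])
    fold_scores[[f]] <- list(scores = te_scores, labels = y[te])
  }
  list(fold_f1 = fold_f1, train_f1 = train_f1, fold_scores = fold_scores)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Stratified k-fold cross-validation of the screening classifiers
#'
#' Folds are assigned at the document level with the label proportion kept.
#' Per fold, the token vocabulary is fitted on training-fold sentences
#' only. For the sentence task, training uses only sentences of
#' ADE-containing training articles while *every* sentence of the test
#' folds is evaluated (flat evaluation).
#'
#' @param corpus An `ade_corpus` with gold labels and entity spans.
#' @param task `"document"` or `"sentence"`.
#' @param dictionaries Optional list (`disease`, `drug`) of dictionaries;
#'   when given, mentions are normalized before featurization.
#' @param config See [evaluation_config()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return An `ade_cv`: `mean_f1`, `sd_f1` (population formula over the k
#'   folds), `fold_f1`, `best_fold`, `pr_curve` (of the best fold),
#'   `folds`, and metadata.
#' @export
cross_validate <- function(corpus, task = c("document", "sentence"),
                           dictionaries = NULL,
                           config = evaluation_config(), k = 5L, seed = 1L) {
  task <- match.arg(task)
  corpus <- prepare_eval_corpus(corpus, dictionaries, config)
  groups <- config$groups %||%
    (if (task == "document") DOC_GROUPS else SENT_GROUPS)
  design <- build_design(corpus, config$tokenizer %||% tokenize_words)
  folds <- stratified_kfold(corpus, k, seed)
  res <- run_cv(design, folds, task, groups, config, seed)
  best <- which.max(res$fold_f1)
  structure(
    list(task = task, mean_f1 = mean(res$fold_f1),
         sd_f1 = sd_pop(res$fold_f1), fold_f1 = res$fold_f1,
         train_f1 = res$train_f1,
         n_eval = vapply(res$fold_scores, function(z) length(z$labels),
                         integer(1)),
         best_fold = best,
         pr_curve = pr_curve(res$fold_scores[[best]]$scores,
                             res$fold_scores[[best]]$labels),
         folds = folds, groups = groups, k = k, seed = seed,
         sd_formula = "population"),
    class = "ade_cv")
}

#' @export
print.ade_cv <- function(x, ...) {
  cat(sprintf("<ade_cv> %s task, %d folds (seed %d): mean F1 %.3f (SD %.4f)\n",
              x$task, x$k, x$seed, x$mean_f1, x$sd_f1))
  invisible(x)
}

#' Feature-group ablation study
#'
#' Removes one feature group at a time and reports the change in mean CV F1
#' against the all-groups baseline, with identical folds and seed
#' throughout. The pseudo-group `"dummy"` (a single all-zero feature) may
#' be named to verify that removing a vacuous group changes nothing.
#'
#' @inheritParams cross_validate
#' @param groups Feature groups to remove, each valid for the task (or
#'   `"dummy"`).
#' @return An `ade_ablation`: data frame (`group`, `f1_without`,
#'   `delta_f1`) with the baseline mean F1 as attribute `baseline_f1`.
#' @export
ablation <- function(corpus, task = c("document", "sentence"),
                     groups, dictionaries = NULL,
                     config = evaluation_config(), k = 5L, seed = 1L) {
  task <- match.arg(task)
  base_groups <- config$groups %||%
    (if (task == "document") DOC_GROUPS else SENT_GROUPS)
  allowed <- c(base_groups, "dummy")
  bad <- setdiff(groups, allowed)
  if (length(bad)) {
    ade_stop("ablation: group '%s' is not valid for the %s task",
             bad[1], task)
  }
  corpus <- prepare_eval_corpus(corpus, dictionaries, config)
  design <- build_design(corpus, config$tokenizer %||% tokenize_words)
  folds <- stratified_kfold(corpus, k, seed)
  baseline <- mean(run_cv(design, folds, task, base_groups, config,
                          seed)$fold_f1)
  f1_without <- vapply(groups, function(g) {
    mean(run_cv(design, folds, task, setdiff(base_groups, g), config,
                seed)$fold_f1)
  }, numeric(1))
  structure(
    data.frame(group = groups, f1_without = unname(f1_without),
               delta_f1 = unname(f1_without) - baseline,
               stringsAsFactors = FALSE),
    baseline_f1 = baseline, seed = seed,
    class = c("ade_ablation", "data.frame"))
}

#' Learning curve over training-set fractions
#'
#' For each fraction, training-fold documents are subsampled (stratified by
#' document label, seeded per fold), the model is retrained and both
#' training and validation F1 are reported. Fraction 1.0 reproduces
#' [cross_validate()]'s mean F1 exactly (same folds and seed). A fraction
#' whose subsample is single-class skips the fold with a warning.
#'
#' @inheritParams cross_validate
#' @param fractions Numeric vector in `(0, 1]`.
#' @return Data frame: `fraction`, `train_f1`, `validation_f1` (means over
#'   folds, `NA` folds dropped).
#' @export
learning_curve <- function(corpus, task = c("document", "sentence"),
                           fractions, dictionaries = NULL,
                           config = evaluation_config(), k = 5L,
                           seed = 1L) {
  task <- match.arg(task)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  corpus <- prepare_eval_corpus(corpus, dictionaries, config)
  groups <- config$groups %||%
    (if (task == "document") DOC_GROUPS else SENT_GROUPS)
  design <- build_design(corpus, config$tokenizer %||% tokenize_words)
  folds <- stratified_kfold(corpus, k, seed)
  rows <- lapply(fractions, function(fr) {
    res <- run_cv(design, folds, task, groups, config, seed, fraction = fr)
    data.frame(fraction = fr,
               train_f1 = mean(res$train_f1, na.rm = TRUE),
               validation_f1 = mean(res$fold_f1, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
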