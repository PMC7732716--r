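# Binary linear classifiers and the hierarchical document -> sentence
# screening pipeline.
#
# Both classifiers are L2-regularized logistic regressions fitted at
# regularization strength lambda = 1/n (glmnet ridge, unstandardized,
# unpenalized intercept), i.e. the objective of a default-parameter
# scikit-learn LogisticRegression (C = 1). Class weights are uniform; the
# sentence task addresses imbalance by training-set restriction instead
# (only sentences of ADE-containing articles are used for training).
# Decision threshold: 0.5 on the probability scale.

fit_logistic <- function(X, y, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    ade_stop("training set contains a single class")
  }
  lam <- max(1 / nrow(X), 1e-8)
  path <- sort(unique(c(0.1, 0.01, lam)), decreasing = TRUE)
  fit <- quiet_small_class(
    glmnet::glmnet(X, factor(y, levels = c(0L, 1L)),
                   family = "binomial", alpha = 0,
                   standardize = FALSE, lambda = path,
                   thresh = 1e-9))
  cf <- stats::coef(fit)[, length(fit$lambda)]
  list(weights = stats::setNames(unname(cf[-1L]), colnames(X)),
       intercept = unname(cf[1L]), lambda = lam,
       seed = as.integer(seed))
}

new_classifier <- function(fit, level, groups, vocab, threshold = 0.5,
                           extra_meta = list()) {
  structure(
    list(weights = fit$weights, intercept = fit$intercept,
         threshold = threshold, level = level, groups = groups,
         vocab = vocab,
         meta = c(list(lambda = fit$lambda, seed = fit$seed), extra_meta)),
    class = "ade_classifier")
}

#' @export
print.ade_classifier <- function(x, ...) {
  cat(sprintf("<ade_classifier> %s level, %d features, threshold %.2f\n",
              x$level, length(x$weights), x$threshold))
  invisible(x)
}

classifier_scores <- function(model, X) {
  w <- model$weights
  common <- intersect(colnames(X), names(w))
  eta <- model$intercept +
    as.numeric(X[, common, drop = FALSE] %*% w[common])
  stats::plogis(eta)
}

#' Train the document-level (ADE-containing article) classifier
#'
#' @param train_articles Training articles with normalized spans and gold
#'   document labels.
#' @param vocab An `ade_vocabulary` fitted on the training articles' texts.
#' @param config List: `groups` (default the three document groups),
#'   `tokenizer`, `binary` (binary indicators instead of counts, default
#'   `FALSE`).
#' @param seed Integer recorded in the model metadata (the fit is
#'   deterministic).
#' @return An `ade_classifier`.
#' @export
train_document_model <- function(train_articles, vocab, config = list(),
                                 seed = 1L) {
  groups <- config$groups %||% DOC_GROUPS
  tokenizer <- config$tokenizer %||% tokenize_words
  design <- build_design(train_articles, tokenizer)
  X <- assemble_design(design, "document", vocab, groups,
                       binary = isTRUE(config$binary))
  fit <- fit_logistic(X, design$doc_labels, seed)
  new_classifier(fit, "document", groups, vocab,
                 extra_meta = list(corpus_hash = ade_hash(design$texts)))
}

#' Train the sentence-level (ADE-suggesting sentence) classifier
#'
#' Training instances are drawn exclusively from articles whose gold
#' document label is positive; this keeps the label proportion workable
#' without reweighting.
#'
#' @inheritParams train_document_model
#' @param config As in [train_document_model()]; `groups` defaults to all
#'   six sentence-level groups.
#' @return An `ade_classifier`.
#' @export
train_sentence_model <- function(train_articles, vocab, config = list(),
                                 seed = 1L) {
  groups <- config$groups %||% SENT_GROUPS
  tokenizer <- config$tokenizer %||% tokenize_words
  pos <- Filter(function(a) a$doc_label == 1L, train_articles)
  if (length(pos) == 0L) {
    ade_stop("train_sentence_model: no ADE-containing articles in training set")
  }
  design <- build_design(pos, tokenizer)
  X <- assemble_design(design, "sentence", vocab, groups,
                       binary = isTRUE(config$binary))
  fit <- fit_logistic(X, design$sent_labels, seed)
  new_classifier(fit, "sentence", groups, vocab,
                 extra_meta = list(corpus_hash = ade_hash(design$texts),
                                   n_train = nrow(X)))
}

#' Screen articles for ADE content
#'
#' Applies the document classifier to every article and the sentence
#' classifier per `mode`: `"pipeline"` (deployment) classifies sentences
#' only inside articles predicted ADE containing; `"flat"` (evaluation)
#' classifies every sentence of every article.
#'
#' @param articles Corpus with normalized spans (labels may be absent/0).
#' @param doc_model,sent_model Trained `ade_classifier`s.
#' @param mode `"pipeline"` or `"flat"`.
#' @param tokenizer See [tokenize_words()].
#' @return List of two data frames: `documents` (`doc_id`, `prob`, `pred`)
#'   and `sentences` (`doc_id`, `sent_id`, `prob`, `pred`).
#' @export
screen <- function(articles, doc_model, sent_model,
                   mode = c("pipeline", "flat"),
                   tokenizer = tokenize_words) {
  mode <- match.arg(mode)
  design <- build_design(articles, tokenizer)
  Xd <- assemble_design(design, "document", doc_model$vocab,
                        doc_model$groups)
  doc_prob <- classifier_scores(doc_model, Xd)
  doc_pred <- as.integer(doc_prob >= doc_model$threshold)
  documents <- data.frame(doc_id = design$doc_ids, prob = doc_prob,
                          pred = doc_pred, stringsAsFactors = FALSE)
  Xs <- assemble_design(design, "sentence", sent_model$vocab,
                        sent_model$groups)
  sent_prob <- classifier_scores(sent_model, Xs)
  sentences <- data.frame(
    doc_id = design$doc_ids[design$sent_doc],
    sent_id = design$sent_pos - 1L,
    prob = sent_prob,
    pred = as.integer(sent_prob >= sent_model$threshold),
    stringsAsFactors = FALSE)
  if (mode == "pipeline") {
    keep_docs <- design$doc_ids[doc_pred == 1L]
    sentences <- sentences[sentences$doc_id %in% keep_docs, , drop = FALSE]
    rownames(sentences) <- NULL
  }
  list(documents = documents, sentences = sentences)
}

#' Export classifier coefficients
#'
#' The interpretability surface of the system: every feature with its
#' weight and feature group, sorted by absolute weight.
#'
#' @param object An `ade_classifier`.
#' @param ... Unused.
#' @return A `data.frame` (`feature`, `group`, `weight`) sorted by
#'   decreasing `abs(weight)`, with the intercept in
#'   `attr(, "intercept")`.
#' @export
coef.ade_classifier <- function(object, ...) {
  out <- data.frame(feature = names(object$weights),
                    group = group_of_features(names(object$weights)),
                    weight = unname(object$weights),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intercept") <- object$intercept
  out
}

#' Rebuild a classifier from exported coefficients
#'
#' Round-trip companion of [coef.ade_classifier()]: the rebuilt model
#' reproduces all probabilities of the original.
#'
#' @param coefs A data frame as returned by [coef.ade_classifier()].
#' @param intercept Intercept (defaults to the attribute on `coefs`).
#' @param template An `ade_classifier` supplying level/groups/vocab/
#'   threshold.
#' @return An `ade_classifier`.
#' @export
classifier_from_coefficients <- function(coefs,
                                         intercept = attr(coefs, "intercept"),
                                         template) {
  m <- template
  m$weights <- stats::setNames(coefs$weight, coefs$feature)[names(template$weights)]
  m$intercept <- intercept
  m
}

#' Write / read a classifier as JSON
#'
#' @param model An `ade_classifier`.
#' @param path File path.
#' @return `path` invisibly; `read_classifier` returns the model.
#' @export
write_classifier <- function(model, path) {
  obj <- list(level = model$level, groups = model$groups,
              threshold = model$threshold,
              intercept = model$intercept,
              weights = as.list(model$weights),
              vocab = list(tokens = model$vocab$tokens,
                           min_count = model$vocab$min_count,
                           fitted_on = model$vocab$fitted_on),
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vocab <- structure(list(tokens = as.character(obj$vocab$tokens),
                          min_count = as.integer(obj$vocab$min_count),
                          fitted_on = obj$vocab$fitted_on),
                     class = "ade_vocabulary")
  structure(
    list(weights = unlist(obj$weights), intercept = obj$intercept,
         threshold = obj$threshold, level = obj$level,
         groups = as.character(obj$groups), vocab = vocab, meta = obj$meta),
    class = "ade_classifier")
}
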