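# Interpretable sparse feature groups for document- and sentence-level
# classification.
#
# Six groups:
#   word_tokens      bag of word tokens (counts; singleton tokens removed)
#   std_name         bag of standard (normalized) disease/drug names
#   sum_name         total disease-mention count and total drug-mention count
#   ctx_word_tokens  word tokens of the previous + next sentence, pooled
#   ctx_std_name     standard names of the previous + next sentence
#   ctx_sum_name     mention totals of the previous + next sentence
# Document vectors use only the first three groups; sentence vectors all six.
# sum_name counts every recognized mention (normalized or not); std_name
# counts only mentions that were normalized, so the two groups stay
# non-redundant. Context at article boundaries is empty (all zero).

DOC_GROUPS <- c("word_tokens", "std_name", "sum_name")
SENT_GROUPS <- c(DOC_GROUPS,
                 "ctx_word_tokens", "ctx_std_name", "ctx_sum_name")

GROUP_PREFIX <- c(word_tokens = "wt", std_name = "std", sum_name = "sum",
                  ctx_word_tokens = "ctx_wt", ctx_std_name = "ctx_std",
                  ctx_sum_name = "ctx_sum")

group_of_features <- function(feature_names) {
  prefix <- sub("\\|.*$", "", feature_names)
  names(GROUP_PREFIX)[match(prefix, GROUP_PREFIX)]
}

#' Default word tokenizer
#'
#' Splits on whitespace after mapping ASCII punctuation and the Japanese
#' full stop / comma to spaces. A tokenizer is any deterministic total
#' function taking a character vector and returning a list with one
#' character vector of tokens per input string; a morphological-analyzer
#' adapter can be plugged in through the same contract.
#'
#' @param x Character vector of texts.
#' @return List of character token vectors, one per element of `x`.
#' @export
tokenize_words <- function(x) {
  y <- gsub("[[:punct:]。、]+", " ", x, perl = TRUE)
  toks <- strsplit(trimws(y), "[[:space:]]+", perl = TRUE)
  lapply(toks, function(t) t[nzchar(t)])
}

#' Fit a token vocabulary on training texts
#'
#' Tokens whose total frequency in `texts` is `<= min_count` are excluded;
#' the default removes words appearing only once. The hash of the fitting
#' texts is stored so downstream harnesses can assert that vocabularies were
#' fitted on training folds only.
#'
#' @param texts Character vector of training texts.
#' @param tokenizer See [tokenize_words()].
#' @param min_count Exclusion threshold (keep frequency `> min_count`).
#' @return An `ade_vocabulary`: sorted `tokens`, `min_count`, `fitted_on`
#'   hash.
#' @export
fit_vocabulary <- function(texts, tokenizer = tokenize_words, min_count = 1L) {
  if (length(texts) == 0L) ade_stop("fit_vocabulary: no texts")
  counts <- table(unlist(tokenizer(texts), use.names = FALSE))
  keep <- names(counts)[counts > min_count]
  structure(
    list(tokens = sort(keep, method = "radix"),
         min_count = as.integer(min_count),
         fitted_on = ade_hash(texts)),
    class = "ade_vocabulary")
}

#' @export
print.ade_vocabulary <- function(x, ...) {
  cat(sprintf("<ade_vocabulary> %d tokens (min_count %d)\n",
              length(x$tokens), x$min_count))
  invisible(x)
}

# ---- corpus-level design ---------------------------------------------------
# All sentence-level raw count matrices are built once per corpus; fold- and
# group-specific design matrices are column subsets, which keeps fold
# vocabularies training-only without re-tokenizing.

build_design <- function(articles, tokenizer = tokenize_words) {
  n_per_doc <- vapply(articles, function(a) length(a$sentences), integer(1))
  n_sent <- sum(n_per_doc)
  sent_doc <- rep.int(seq_along(articles), n_per_doc)
  sent_pos <- unlist(lapply(n_per_doc, seq_len), use.names = FALSE) # 1-based
  texts <- corpus_sentence_texts(articles)
  toks <- tokenizer(texts)
  all_tokens <- sort(unique(unlist(toks, use.names = FALSE)), method = "radix")
  ti <- match(unlist(toks, use.names = FALSE), all_tokens)
  ri <- rep.int(seq_len(n_sent), lengths(toks))
  M_tok <- Matrix::sparseMatrix(i = ri, j = ti, x = 1,
                                dims = c(n_sent, length(all_tokens)))
  # entity mention tables
  span_rows <- integer(0); span_type <- character(0); span_std <- character(0)
  k <- 0L
  for (a in articles) for (s in a$sentences) {
    k <- k + 1L
    if (nrow(s$spans)) {
      span_rows <- c(span_rows, rep.int(k, nrow(s$spans)))
      span_type <- c(span_type, s$spans$etype)
      span_std <- c(span_std, s$spans$standard)
    }
  }
  standards <- sort(unique(span_std[!is.na(span_std)]), method = "radix")
  ok <- !is.na(span_std)
  M_std <- Matrix::sparseMatrix(
    i = span_rows[ok], j = match(span_std[ok], standards), x = 1,
    dims = c(n_sent, length(standards)))
  M_sum <- Matrix::sparseMatrix(
    i = span_rows, j = match(span_type, c("disease", "drug")), x = 1,
    dims = c(n_sent, 2L))
  # neighbor-pooling operator: row i sums rows i-1 and i+1 within the article
  prev_ok <- which(sent_pos > 1L)
  next_ok <- which(sent_pos < n_per_doc[sent_doc])
  S <- Matrix::sparseMatrix(
    i = c(prev_ok, next_ok), j = c(prev_ok - 1L, next_ok + 1L), x = 1,
    dims = c(n_sent, n_sent))
  # document aggregation operator
  A <- Matrix::sparseMatrix(i = sent_doc, j = seq_len(n_sent), x = 1,
                            dims = c(length(articles), n_sent))
  list(
    tokens = all_tokens, standards = standards,
    M_tok = M_tok, M_std = M_std, M_sum = M_sum,
    M_ctx_tok = S %*% M_tok, M_ctx_std = S %*% M_std, M_ctx_sum = S %*% M_sum,
    A = A, sent_doc = sent_doc, sent_pos = sent_pos,
    doc_ids = vapply(articles, function(a) a$doc_id, character(1)),
    doc_labels = doc_labels(articles),
    sent_labels = unlist(lapply(articles, function(a) {
      vapply(a$sentences, function(s) s$sent_label, integer(1))
    }), use.names = FALSE),
    texts = texts
  )
}

name_cols <- function(m, prefix, names) {
  # paste0() maps zero-length input to "", not character(0)
  colnames(m) <- if (length(names)) paste0(prefix, "|", names)
                 else character(0)
  m
}

group_matrix <- function(design, group, level, vocab) {
  vt <- match(vocab$tokens, design$tokens)   # NA = token absent from corpus
  subset_tok <- function(m) {
    out <- m[, vt[!is.na(vt)], drop = FALSE]
    name_cols(out, GROUP_PREFIX[[group]], design$tokens[vt[!is.na(vt)]])
  }
  m <- switch(group,
    word_tokens = subset_tok(design$M_tok),
    ctx_word_tokens = subset_tok(design$M_ctx_tok),
    std_name = name_cols(design$M_std, "std", design$standards),
    ctx_std_name = name_cols(design$M_ctx_std, "ctx_std", design$standards),
    sum_name = name_cols(design$M_sum, "sum", c("disease", "drug")),
    ctx_sum_name = name_cols(design$M_ctx_sum, "ctx_sum",
                             c("disease", "drug")),
    dummy = {
      z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nrow(design$M_tok), 1L))
      name_cols(z, "dummy", "zero")
    },
    ade_stop("unknown feature group '%s'", group)
  )
  if (level == "document") m <- design$A %*% m
  m
}

assemble_design <- function(design, level = c("document", "sentence"),
                            vocab, groups, binary = FALSE) {
  level <- match.arg(level)
  allowed <- c(if (level == "document") DOC_GROUPS else SENT_GROUPS, "dummy")
  bad <- setdiff(groups, allowed)
  if (length(bad)) {
    ade_stop("feature group '%s' is not valid for the %s task", bad[1], level)
  }
  mats <- lapply(groups, group_matrix, design = design, level = level,
                 vocab = vocab)
  X <- do.call(cbind, mats)
  if (binary) X@x <- pmin(X@x, 1)
  X
}

features_from_row <- function(X, row) {
  v <- X[row, ]
  nz <- which(v != 0)
  vals <- stats::setNames(as.numeric(v[nz]), colnames(X)[nz])
  structure(
    list(values = vals,
         groups = stats::setNames(group_of_features(names(vals)),
                                  names(vals))),
    class = "ade_features")
}

#' @export
print.ade_features <- function(x, ...) {
  cat(sprintf("<ade_features> %d nonzero features in groups {%s}\n",
              length(x$values), paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Feature vector for one article (document-level task)
#'
#' Builds the three document-level groups: `word_tokens` (token counts over
#' the whole article, out-of-vocabulary tokens dropped), `std_name` (count
#' per standard name; unnormalized mentions contribute nothing) and
#' `sum_name` (total disease-mention count, total drug-mention count).
#'
#' @param article An `ade_article` whose spans have been normalized.
#' @param vocab An `ade_vocabulary` fitted on training texts.
#' @param tokenizer See [tokenize_words()].
#' @return An `ade_features` object: named sparse `values` plus a parallel
#'   `groups` tag vector.
#' @export
featurize_document <- function(article, vocab, tokenizer = tokenize_words) {
  design <- build_design(list(article), tokenizer)
  X <- assemble_design(design, "document", vocab, DOC_GROUPS)
  features_from_row(X, 1L)
}

#' Feature vector for one sentence (sentence-level task)
#'
#' In-sentence groups as in [featurize_document()], computed on sentence
#' `i`, plus context groups (`ctx_*`) pooled over the previous and next
#' sentence; a missing neighbor at the article boundary contributes nothing.
#'
#' @param article An `ade_article` with normalized spans.
#' @param i 0-based sentence index.
#' @param vocab,tokenizer As in [featurize_document()].
#' @return An `ade_features` object over the six sentence-level groups.
#' @export
featurize_sentence <- function(article, i, vocab,
                               tokenizer = tokenize_words) {
  if (i < 0L || i >= length(article$sentences)) {
    ade_stop("sentence index %d out of range [0, %d)", i,
             length(article$sentences))
  }
  design <- build_design(list(article), tokenizer)
  X <- assemble_design(design, "sentence", vocab, SENT_GROUPS)
  features_from_row(X, i + 1L)
}
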