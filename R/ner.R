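# Character-level named entity recognition of disease and drug mentions.
#
# Sentences are tagged per character over the 5-tag IOB2 space
# {B-disease, I-disease, B-drug, I-drug, O}. The labeler is a maximum-entropy
# tagger: one joint multinomial logistic regression (ridge) over a sparse
# indicator template of character identities, character bigrams and Unicode
# script classes in a +/-window context, decoded left to right under the
# IOB2 well-formedness constraint. Gold spans can always be used instead of
# a trained model ("oracle" mode) so downstream modules are testable
# independently of tagger quality.

NER_TAGS <- c("B-disease", "I-disease", "B-drug", "I-drug", "O")

BOS <- "«"
EOS <- "»"

#' Encode a sentence's entity spans as character-level IOB2 tags
#'
#' @param s An `ade_sentence` with valid, non-overlapping spans.
#' @return Character vector of tags, one per character of `s$text`.
#' @export
encode_iob2 <- function(s) {
  validate_sentence(s, "encode_iob2")
  n <- nchar(s$text)
  tags <- rep("O", n)
  sp <- s$spans
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      tags[sp$start[i] + 1L] <- paste0("B-", sp$etype[i])
      if (sp$end[i] - sp$start[i] > 1L) {
        tags[(sp$start[i] + 2L):sp$end[i]] <- paste0("I-", sp$etype[i])
      }
    }
  }
  tags
}

#' Repair an ill-formed IOB2 tag sequence
#'
#' An `I-x` tag not preceded by `B-x` or `I-x` is rewritten to `B-x`
#' (standard IOB2 repair), which makes decoding total and deterministic.
#'
#' @param tags Character vector of IOB2 tags.
#' @return A well-formed tag vector.
#' @export
repair_iob2 <- function(tags) {
  if (length(tags) == 0L) return(tags)
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      etype <- substring(tags[i], 3L)
      ok <- i > 1L && tags[i - 1L] %in% paste0(c("B-", "I-"), etype)
      if (!ok) tags[i] <- paste0("B-", etype)
    }
  }
  tags
}

#' Decode IOB2 tags into entity spans
#'
#' Maximal `B-x (I-x)*` runs become spans; ill-formed tags are repaired
#' first via [repair_iob2()].
#'
#' @param tags Character vector of tags.
#' @param text The tagged text; `nchar(text)` must equal `length(tags)`.
#' @return An entity span table (0-based half-open offsets, surfaces
#'   filled from `text`).
#' @export
decode_iob2 <- function(tags, text) {
  if (length(tags) != nchar(text)) {
    ade_stop("decode_iob2: %d tags for text of length %d",
             length(tags), nchar(text))
  }
  if (!all(tags %in% NER_TAGS)) {
    ade_stop("decode_iob2: unknown tag '%s'", setdiff(tags, NER_TAGS)[1])
  }
  tags <- repair_iob2(tags)
  starts <- integer(0); ends <- integer(0); etypes <- character(0)
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    if (startsWith(tags[i], "B-")) {
      etype <- substring(tags[i], 3L)
      j <- i + 1L
      while (j <= n && tags[j] == paste0("I-", etype)) j <- j + 1L
      starts <- c(starts, i - 1L); ends <- c(ends, j - 1L)
      etypes <- c(etypes, etype)
      i <- j
    } else i <- i + 1L
  }
  if (length(starts) == 0L) return(entity_spans())
  entity_spans(starts, ends, etypes,
               surface = substring(text, starts + 1L, ends))
}

# Feature template: a fixed-width matrix of feature strings, one row per
# character position. Unigrams and bigrams of character identity within the
# window, script classes and script-class transitions.
char_feature_matrix <- function(text, window = 2L) {
  ch <- chars_of(text)
  n <- length(ch)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = 1))
  pad <- c(rep(BOS, window), ch, rep(EOS, window))
  stopifnot(window >= 1L)
  at <- function(k) pad[seq_len(n) + window + k]  # offset k from position
  cls <- classify_codepoints(utf8ToInt(paste(ch, collapse = "")))
  pcls <- c(rep("bos", window), cls, rep("eos", window))
  cat_ <- function(k) pcls[seq_len(n) + window + k]
  offs <- setdiff(seq(-window, window), 0L)
  cols <- c(
    list(paste0("c0=", at(0L))),
    lapply(offs, function(k) paste0("c", sprintf("%+d", k), "=", at(k))),
    list(
      paste0("b-1=", at(-1L), at(0L)), paste0("b+1=", at(0L), at(1L)),
      paste0("t0=", cat_(0L)),
      paste0("t-1=", cat_(-1L)), paste0("t+1=", cat_(1L)),
      paste0("tt-1=", cat_(-1L), ">", cat_(0L)),
      paste0("tt+1=", cat_(0L), ">", cat_(1L))
    )
  )
  do.call(cbind, cols)
}

#' Character context features for the tagger
#'
#' @param text Sentence text.
#' @param i 0-based character position, `0 <= i < nchar(text)`.
#' @param window Context half-width in characters.
#' @return Character vector of feature strings (e.g. `"c0=M"`,
#'   `"tt-1=latin>kanji"`); out-of-range context positions contribute
#'   explicit padding symbols.
#' @export
char_features <- function(text, i, window = 2L) {
  stopifnot(i >= 0L, i < nchar(text))
  unname(char_feature_matrix(text, window)[i + 1L, ])
}

corpus_sentence_texts <- function(articles) {
  unlist(lapply(articles, function(a) {
    vapply(a$sentences, function(s) s$text, character(1))
  }), use.names = FALSE)
}

# Build the sparse design matrix for a set of texts given a fixed feature
# vocabulary (training: vocab = NULL derives it; prediction: unseen feature
# strings are dropped).
ner_design <- function(texts, window, vocab = NULL) {
  fmats <- lapply(texts, char_feature_matrix, window = window)
  nchars <- vapply(fmats, nrow, integer(1))
  feats <- unlist(fmats, use.names = FALSE) # column-major: per template col
  rows <- unlist(lapply(seq_along(fmats), function(k) {
    offset <- if (k == 1L) 0L else sum(nchars[seq_len(k - 1L)])
    rep.int(offset + seq_len(nchars[k]), ncol(fmats[[k]]))
  }), use.names = FALSE)
  if (is.null(vocab)) vocab <- sort(unique(feats), method = "radix")
  j <- match(feats, vocab)
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(i = rows[keep], j = j[keep], x = 1,
                            dims = c(sum(nchars), length(vocab)))
  list(X = X, vocab = vocab, nchars = nchars)
}

#' Train the character-level entity tagger
#'
#' Fits one joint multinomial ridge logistic regression over the IOB2 tag
#' space on every character of every sentence in the training articles
#' (gold spans required). Training is deterministic given the corpus.
#'
#' @param train List of `ade_article`s with gold spans.
#' @param config List; `window` (context half-width, default 2) is the only
#'   recognized entry.
#' @param seed Integer recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return An `ade_ner_model`.
#' @export
train_ner <- function(train, config = list(), seed = 1L) {
  if (length(train) == 0L) ade_stop("train_ner: empty training set")
  window <- as.integer(config$window %||% 2L)
  texts <- corpus_sentence_texts(train)
  tags <- unlist(lapply(train, function(a) {
    lapply(a$sentences, encode_iob2)
  }), use.names = FALSE)
  des <- ner_design(texts, window)
  y <- factor(tags, levels = NER_TAGS[NER_TAGS %in% unique(tags)])
  fit <- NULL
  lam <- NULL
  if (nlevels(y) > 1L) {
    lam <- max(1 / nrow(des$X), 1e-6)
    path <- sort(unique(c(0.1, 0.01, lam)), decreasing = TRUE)
    fit <- quiet_small_class(
      glmnet::glmnet(des$X, y,
                     family = if (nlevels(y) > 2L) "multinomial" else "binomial",
                     alpha = 0, standardize = FALSE, lambda = path))
  }
  structure(
    list(fit = fit, classes = levels(y), vocab = des$vocab, window = window,
         lambda = lam,
         meta = list(seed = as.integer(seed), corpus_hash = ade_hash(texts),
                     template = "char uni/bigram +/-2, script classes")),
    class = "ade_ner_model")
}

ner_class_probs <- function(model, texts) {
  des <- ner_design(texts, model$window, vocab = model$vocab)
  k <- length(model$classes)
  if (is.null(model$fit)) {
    p <- matrix(1, nrow(des$X), 1, dimnames = list(NULL, model$classes))
  } else if (k == 2L) {
    p2 <- stats::predict(model$fit, des$X, type = "response")
    last <- ncol(p2)
    p <- cbind(1 - p2[, last], p2[, last])
    colnames(p) <- model$classes
  } else {
    p3 <- stats::predict(model$fit, des$X, type = "response")
    p <- p3[, , dim(p3)[3]]
    colnames(p) <- model$classes
  }
  list(p = p, nchars = des$nchars)
}

# Greedy left-to-right decoding under the IOB2 constraint: I-x is only
# admissible directly after B-x or I-x; the highest-probability admissible
# tag is taken at each position.
constrained_decode <- function(p, classes) {
  n <- nrow(p)
  tags <- character(n)
  prev <- "O"
  for (i in seq_len(n)) {
    ok <- !startsWith(classes, "I-") |
      (prev %in% paste0(c("B-", "I-"), substring(classes, 3L)) &
         startsWith(classes, "I-"))
    probs <- p[i, ]
    probs[!ok] <- -Inf
    tags[i] <- classes[which.max(probs)]
    prev <- tags[i]
  }
  tags
}

#' Predict entity spans in one sentence
#'
#' @param model An `ade_ner_model` from [train_ner()].
#' @param sentence_text The text to tag.
#' @return An entity span table (non-overlapping, surfaces filled,
#'   `standard` all `NA`; normalization is a separate step).
#' @export
predict_spans <- function(model, sentence_text) {
  stopifnot(inherits(model, "ade_ner_model"))
  if (!nzchar(sentence_text)) return(entity_spans())
  out <- ner_class_probs(model, sentence_text)
  tags <- constrained_decode(out$p, model$classes)
  decode_iob2(tags, sentence_text)
}

#' Run the tagger over a whole corpus
#'
#' Replaces every sentence's spans with predicted spans (labels untouched).
#' With `model = "gold"`, gold spans are kept as-is (oracle mode).
#'
#' @param model An `ade_ner_model`, or the string `"gold"`.
#' @param articles An `ade_corpus`.
#' @return The corpus with predicted spans.
#' @export
predict_corpus_spans <- function(model, articles) {
  if (identical(model, "gold")) return(articles)
  texts <- corpus_sentence_texts(articles)
  out <- ner_class_probs(model, texts)
  stops <- cumsum(out$nchars)
  starts <- c(1L, stops[-length(stops)] + 1L)
  k <- 0L
  res <- lapply(articles, function(a) {
    a$sentences <- lapply(a$sentences, function(s) {
      k <<- k + 1L
      rows <- starts[k]:stops[k]
      tags <- constrained_decode(out$p[rows, , drop = FALSE], model$classes)
      s$spans <- decode_iob2(tags, s$text)
      s
    })
    a
  })
  structure(res, class = "ade_corpus")
}

#' Span-level precision/recall/F1 of predicted against gold spans
#'
#' Exact match on (start, end, type), micro-averaged over all sentences.
#'
#' @param predicted,gold Corpora of identical shape (predicted spans vs
#'   gold spans).
#' @return Named numeric: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
span_prf <- function(predicted, gold) {
  tp <- fp <- fn <- 0L
  for (d in seq_along(gold)) {
    for (s in seq_along(gold[[d]]$sentences)) {
      g <- gold[[d]]$sentences[[s]]$spans
      p <- predicted[[d]]$sentences[[s]]$spans
      gk <- paste(g$start, g$end, g$etype)
      pk <- paste(p$start, p$end, p$etype)
      tp <- tp + sum(pk %in% gk)
      fp <- fp + sum(!pk %in% gk)
      fn <- fn + sum(!gk %in% pk)
    }
  }
  m <- prf(tp, fp, fn)
  c(m, tp = tp, fp = fp, fn = fn)
}

#' Save / load a trained tagger
#'
#' @param model An `ade_ner_model`.
#' @param path File path.
#' @return `path` invisibly; `load_ner_model` returns the model.
#' @export
save_ner_model <- function(model, path) {
  stopifnot(inherits(model, "ade_ner_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ner_model
#' @export
load_ner_model <- function(path) readRDS(path)
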