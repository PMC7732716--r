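# Corpus data model: Article / Sentence / EntitySpan / Dictionary.
#
# Character offsets are 0-based half-open throughout ([start, end)), so a
# span's surface is substr(text, start + 1, end).

#' Construct an entity span table
#'
#' Entity spans locate disease and drug mentions inside one sentence, using
#' 0-based half-open character offsets. `standard` holds the normalized
#' (dictionary standard) name, or `NA` when the mention was not normalized.
#'
#' @param start,end Integer character offsets, 0-based half-open.
#' @param etype `"disease"` or `"drug"`, recycled.
#' @param surface Surface strings; must equal the sentence text slice.
#' @param standard Standard names or `NA` (default).
#' @return A `data.frame` with columns `start`, `end`, `etype`, `surface`,
#'   `standard`.
#' @export
entity_spans <- function(start = integer(0), end = integer(0),
                         etype = character(0), surface = character(0),
                         standard = NA_character_) {
  n <- length(start)
  data.frame(
    start = as.integer(start),
    end = as.integer(end),
    etype = as.character(rep_len(etype, n)),
    surface = as.character(rep_len(surface, n)),
    standard = as.character(rep_len(standard, if (n) n else 0L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a sentence
#'
#' @param text Sentence text (non-empty).
#' @param sent_label Binary ADE-suggesting label (0/1).
#' @param criterion `"A"` (adverse event after a drug prescription),
#'   `"B"` (explicitly stated suspicious ADE) or `"none"`. A criterion of
#'   `"A"`/`"B"` forces `sent_label = 1`; `"none"` forces `sent_label = 0`.
#' @param spans Entity span table, see [entity_spans()].
#' @param sent_id 0-based position within the article (filled by
#'   [article()] when `NA`).
#' @return An object of class `ade_sentence`.
#' @export
sentence <- function(text, sent_label = 0L, criterion = "none",
                     spans = entity_spans(), sent_id = NA_integer_) {
  s <- structure(
    list(
      sent_id = as.integer(sent_id),
      text = as.character(text),
      sent_label = as.integer(sent_label),
      criterion = as.character(criterion),
      spans = spans
    ),
    class = "ade_sentence"
  )
  validate_spans(s$spans, s$text, "sentence")
  s
}

#' Construct an article
#'
#' The document label is *derived*: an article is ADE containing (label 1)
#' if and only if at least one of its sentences is ADE suggesting.
#'
#' @param doc_id Unique document identifier.
#' @param sentences List of [sentence()] objects; `sent_id`s are assigned
#'   from position.
#' @param raw_text Original article text; defaults to the concatenation of
#'   the sentence texts.
#' @return An object of class `ade_article`.
#' @export
article <- function(doc_id, sentences, raw_text = NULL) {
  sentences <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    s$sent_id <- i - 1L
    s
  })
  labels <- vapply(sentences, function(s) s$sent_label, integer(1))
  structure(
    list(
      doc_id = as.character(doc_id),
      raw_text = as.character(raw_text %||%
        paste(vapply(sentences, function(s) s$text, character(1)),
              collapse = "")),
      doc_label = as.integer(any(labels == 1L)),
      sentences = sentences
    ),
    class = "ade_article"
  )
}

#' Construct a corpus
#'
#' @param articles List of [article()] objects.
#' @return An object of class `ade_corpus` (a validated list of articles).
#' @export
corpus <- function(articles) {
  x <- structure(articles, class = "ade_corpus")
  validate_corpus(x)
  x
}

validate_spans <- function(spans, text, where) {
  required <- c("start", "end", "etype", "surface", "standard")
  if (!all(required %in% names(spans))) {
    ade_stop("%s: span table misses columns %s", where,
             paste(setdiff(required, names(spans)), collapse = ", "))
  }
  if (nrow(spans) == 0L) return(invisible(TRUE))
  n <- nchar(text)
  bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
  if (any(bad)) {
    ade_stop("%s: span [%d,%d) out of bounds for text of length %d",
             where, spans$start[which(bad)[1]], spans$end[which(bad)[1]], n)
  }
  if (!all(spans$etype %in% c("disease", "drug"))) {
    ade_stop("%s: span etype must be 'disease' or 'drug'", where)
  }
  o <- order(spans$start)
  if (is.unsorted(spans$start)) {
    ade_stop("%s: spans must be sorted by start offset", where)
  }
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    ade_stop("%s: spans overlap", where)
  }
  slice <- substring(text, spans$start + 1L, spans$end)
  if (!all(slice == spans$surface)) {
    i <- which(slice != spans$surface)[1]
    ade_stop("%s: span surface '%s' does not match text slice '%s'",
             where, spans$surface[i], slice[i])
  }
  invisible(TRUE)
}

validate_sentence <- function(s, where) {
  if (!nzchar(s$text)) ade_stop("%s: empty sentence text", where)
  if (!s$criterion %in% c("A", "B", "none")) {
    ade_stop("%s: criterion must be 'A', 'B' or 'none'", where)
  }
  if (s$criterion %in% c("A", "B") && s$sent_label != 1L) {
    ade_stop("%s: criterion '%s' requires sent_label = 1", where, s$criterion)
  }
  if (s$criterion == "none" && s$sent_label != 0L) {
    ade_stop("%s: criterion 'none' requires sent_label = 0", where)
  }
  validate_spans(s$spans, s$text, where)
  invisible(TRUE)
}

validate_article <- function(a) {
  where <- sprintf("article '%s'", a$doc_id)
  if (!nzchar(a$doc_id)) ade_stop("article with empty doc_id")
  if (length(a$sentences) == 0L) ade_stop("%s: no sentences", where)
  ids <- vapply(a$sentences, function(s) s$sent_id, integer(1))
  if (!identical(ids, seq_along(a$sentences) - 1L)) {
    ade_stop("%s: sent_id must be the 0-based sentence position", where)
  }
  for (s in a$sentences) {
    validate_sentence(s, sprintf("%s, sentence %d", where, s$sent_id))
  }
  labels <- vapply(a$sentences, function(s) s$sent_label, integer(1))
  if (a$doc_label != as.integer(any(labels == 1L))) {
    ade_stop(
      "%s: doc_label %d inconsistent with sentence labels (rule: ADE containing iff some sentence is ADE suggesting)",
      where, a$doc_label)
  }
  invisible(TRUE)
}

#' Validate a corpus against the data-model invariants
#'
#' Checks uniqueness of `doc_id`s and, per article: non-empty ordered
#' sentences, criterion/label consistency, and span well-formedness
#' (in-bounds, sorted, non-overlapping, surface equal to the text slice),
#' and that `doc_label` equals the indicator of any positive sentence.
#'
#' @param x An `ade_corpus`.
#' @return `x`, invisibly; errors name the offending article and rule.
#' @export
validate_corpus <- function(x) {
  ids <- vapply(x, function(a) a$doc_id, character(1))
  if (anyDuplicated(ids)) {
    ade_stop("duplicate doc_id '%s'", ids[duplicated(ids)][1])
  }
  for (a in x) validate_article(a)
  invisible(x)
}

doc_labels <- function(corpus) {
  vapply(corpus, function(a) a$doc_label, integer(1))
}

#' @export
print.ade_corpus <- function(x, ...) {
  n_sent <- sum(vapply(x, function(a) length(a$sentences), integer(1)))
  cat(sprintf("<ade_corpus> %d articles (%d ADE containing), %d sentences\n",
              length(x), sum(doc_labels(x)), n_sent))
  invisible(x)
}

#' @export
print.ade_article <- function(x, ...) {
  cat(sprintf("<ade_article> '%s' label=%d, %d sentences\n",
              x$doc_id, x$doc_label, length(x$sentences)))
  invisible(x)
}
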