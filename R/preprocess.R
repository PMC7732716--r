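# Text cleaning and sentence segmentation.
#
# Segmentation rule: split after the Japanese full stop (U+3002) always, and
# after an ASCII period only when the immediately preceding character is a
# Japanese letter (hiragana U+3040-309F, katakana U+30A0-30FF, CJK unified
# ideograph U+4E00-9FFF). This keeps decimal numbers ("3.5") and Latin
# abbreviations intact while segmenting Japanese prose. Delimiters stay
# attached to the preceding sentence so that joining the output reproduces
# the input exactly. Newlines are ordinary whitespace, not boundaries (OCR
# line breaks are unreliable).

#' Remove stray symbols from raw article text
#'
#' OCR output of medical articles carries symbols (by default `$` and `^`)
#' that do not occur in the source text; they are dropped, all other
#' characters are preserved in order.
#'
#' @param raw Input string.
#' @param strip_set Character vector of single characters to remove.
#' @return The cleaned string.
#' @export
clean_text <- function(raw, strip_set = c("$", "^")) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (length(strip_set) == 0L || !nzchar(raw)) return(raw)
  ch <- chars_of(raw)
  paste(ch[!ch %in% strip_set], collapse = "")
}

#' Segment text into sentences
#'
#' @param text A (cleaned) string.
#' @return Character vector of sentences, delimiters attached; empty
#'   segments dropped. `paste(out, collapse = "")` equals `text`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(character(0))
  cp <- utf8ToInt(text)
  n <- length(cp)
  brk <- cp == 0x3002L
  ascii_period <- cp == 0x2EL
  if (n > 1L) {
    prev_jp <- c(FALSE, is_japanese_codepoint(cp[-n]))
    brk <- brk | (ascii_period & prev_jp)
  }
  ends <- which(brk)
  if (length(ends) == 0L || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- substring(text, starts, ends)
  out[nzchar(out)]
}

#' Preprocess a raw article into an unlabeled corpus article
#'
#' Convenience wrapper: clean, segment, wrap into the corpus data model
#' with all labels 0 (for inference-only ingestion).
#'
#' @param doc_id Document identifier.
#' @param raw Raw article text.
#' @param strip_set Passed to [clean_text()].
#' @return An `ade_article` with unlabeled sentences.
#' @export
preprocess_article <- function(doc_id, raw, strip_set = c("$", "^")) {
  cleaned <- clean_text(raw, strip_set)
  texts <- split_sentences(cleaned)
  if (length(texts) == 0L) ade_stop("article '%s': no sentences after preprocessing", doc_id)
  article(doc_id, lapply(texts, sentence), raw_text = cleaned)
}
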