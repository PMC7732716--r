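`%||%` <- function(a, b) if (is.null(a)) b else a

ade_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Hash an object for provenance bookkeeping
#'
#' Used to record which texts a [fit_vocabulary()] was fitted on so the
#' cross-validation harness can assert the absence of train/test leakage.
#'
#' @param x Any R object.
#' @return A character scalar hash.
#' @keywords internal
ade_hash <- function(x) rlang::hash(x)

# Unicode script classes used by both sentence segmentation and the NER
# feature template. Operates on integer code points, vectorized.
classify_codepoints <- function(cp) {
  out <- rep("symbol", length(cp))
  out[cp >= 0x30 & cp <= 0x39] <- "digit"
  out[(cp >= 0x41 & cp <= 0x5A) | (cp >= 0x61 & cp <= 0x7A)] <- "latin"
  out[cp %in% c(0x20, 0x09, 0x0A, 0x0D)] <- "space"
  out[cp >= 0x3040 & cp <= 0x309F] <- "hiragana"
  out[cp >= 0x30A0 & cp <= 0x30FF] <- "katakana"
  out[cp >= 0x4E00 & cp <= 0x9FFF] <- "kanji"
  out
}

# Japanese letters = hiragana, katakana, CJK unified ideographs.
is_japanese_codepoint <- function(cp) {
  (cp >= 0x3040 & cp <= 0x309F) |
    (cp >= 0x30A0 & cp <= 0x30FF) |
    (cp >= 0x4E00 & cp <= 0x9FFF)
}

# glmnet emits an advisory warning when a class has < 8 observations; that
# is routine for deliberately tiny training sets (learning curves, toy
# fits), so it is muffled. All other warnings propagate.
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Split a string into single characters (UTF-8 aware).
chars_of <- function(x) {
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = FALSE)[[1]]
}
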