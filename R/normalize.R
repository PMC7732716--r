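# Dictionary normalization of extracted mentions by thresholded
# edit-distance similarity.
#
# similarity(a, b) = 1 - Levenshtein(a, b) / max(nchar(a), nchar(b)):
# bounded in [0, 1], symmetric, 1 iff the strings are equal, and
# length-scale free. A mention is replaced by the standard name of the
# dictionary surface with the highest similarity, provided that similarity
# strictly exceeds the threshold (default 0.3); otherwise it is left
# unnormalized. Ties are broken by the lexicographically smallest surface
# form, so results do not depend on dictionary file order.

#' Edit-distance string similarity
#'
#' @param a,b Non-empty strings (vectorized, recycled).
#' @return Numeric similarity in `[0, 1]`.
#' @export
similarity <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    ade_stop("similarity() requires non-empty strings")
  }
  d <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b, USE.NAMES = FALSE)
  1 - d / pmax(nchar(a), nchar(b))
}

# Similarity of each of `surfaces` against every dictionary surface; returns
# an length(surfaces) x length(dict_surfaces) matrix. Single adist call.
similarity_matrix <- function(surfaces, dict_surfaces) {
  d <- utils::adist(surfaces, dict_surfaces)
  len <- outer(nchar(surfaces), nchar(dict_surfaces), pmax)
  1 - d / len
}

# Best match per surface under the strict threshold rule; returns the
# standard name or NA. Ties among equal-similarity candidates go to the
# lexicographically smallest dictionary surface (C collation).
match_standards <- function(surfaces, dict, threshold) {
  if (length(surfaces) == 0L) return(character(0))
  if (length(dict$entries) == 0L) return(rep(NA_character_, length(surfaces)))
  ds <- names(dict$entries)
  ord <- order(ds, method = "radix")   # lexicographic, locale-independent
  ds <- ds[ord]
  std <- unname(dict$entries[ord])
  sim <- similarity_matrix(surfaces, ds)
  vapply(seq_along(surfaces), function(i) {
    best <- max(sim[i, ])
    if (best > threshold) std[which.max(sim[i, ])] else NA_character_
  }, character(1))
}

#' Normalize one entity mention against a dictionary
#'
#' @param span A one-row entity span table (see [entity_spans()]).
#' @param dict An `ade_dictionary` of the same entity type.
#' @param threshold Similarity threshold; the best match must *exceed* it
#'   (strict `>`). Default 0.3.
#' @return The span with its `standard` column filled, or `NA` when no
#'   dictionary surface is similar enough (or the dictionary is empty).
#' @export
normalize_mention <- function(span, dict, threshold = 0.3) {
  stopifnot(nrow(span) == 1L)
  if (!identical(span$etype, dict$etype)) {
    ade_stop("normalize_mention: span etype '%s' but dictionary etype '%s'",
             span$etype, dict$etype)
  }
  span$standard <- match_standards(span$surface, dict, threshold)
  span
}

#' Normalize every mention in a corpus
#'
#' Applies [normalize_mention()] to all disease and drug spans, batched over
#' unique surface forms.
#'
#' @param corpus An `ade_corpus`.
#' @param dictionaries List with elements `disease` and `drug`
#'   (`ade_dictionary` objects).
#' @param threshold Similarity threshold (strict), default 0.3.
#' @return The corpus with span `standard` columns filled where a match
#'   exceeded the threshold.
#' @export
normalize_corpus <- function(corpus, dictionaries, threshold = 0.3) {
  stopifnot(all(c("disease", "drug") %in% names(dictionaries)))
  # one lookup table per etype over unique surfaces in the corpus
  all_spans <- unlist(lapply(corpus, function(a) {
    lapply(a$sentences, function(s) s$spans[, c("surface", "etype")])
  }), recursive = FALSE)
  all_spans <- do.call(rbind, all_spans)
  lut <- list()
  for (et in c("disease", "drug")) {
    uniq <- unique(all_spans$surface[all_spans$etype == et])
    lut[[et]] <- stats::setNames(
      match_standards(uniq, dictionaries[[et]], threshold), uniq)
  }
  out <- lapply(corpus, function(a) {
    a$sentences <- lapply(a$sentences, function(s) {
      if (nrow(s$spans)) {
        s$spans$standard <- ifelse(
          s$spans$etype == "disease",
          lut$disease[s$spans$surface],
          lut$drug[s$spans$surface])
        s$spans$standard <- unname(s$spans$standard)
      }
      s
    })
    a
  })
  structure(out, class = "ade_corpus")
}
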