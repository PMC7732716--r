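# Corpus and dictionary I/O.
#
# Corpus interchange format: JSON lines, one article per line, UTF-8, with a
# required schema_version field. Dictionaries: 2-column TSV (surface TAB
# standard), no header, UTF-8.

CORPUS_SCHEMA_VERSION <- "1.0"

record_to_article <- function(rec, line) {
  need <- c("schema_version", "doc_id", "raw_text", "doc_label", "sentences")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    ade_stop("line %d: record misses field(s) %s", line,
             paste(miss, collapse = ", "))
  }
  if (!identical(as.character(rec$schema_version), CORPUS_SCHEMA_VERSION)) {
    ade_stop("line %d: unsupported schema_version '%s' (expected '%s')",
             line, rec$schema_version, CORPUS_SCHEMA_VERSION)
  }
  sents <- lapply(rec$sentences, function(s) {
    sp <- s$spans %||% list()
    spans <- entity_spans(
      start = vapply(sp, function(z) as.integer(z$start), integer(1)),
      end = vapply(sp, function(z) as.integer(z$end), integer(1)),
      etype = vapply(sp, function(z) as.character(z$etype), character(1)),
      surface = vapply(sp, function(z) as.character(z$surface), character(1)),
      standard = vapply(sp, function(z) {
        if (is.null(z$standard)) NA_character_ else as.character(z$standard)
      }, character(1))
    )
    sentence(
      text = s$text, sent_label = s$sent_label %||% 0L,
      criterion = s$criterion %||% "none", spans = spans
    )
  })
  a <- article(rec$doc_id, sents, raw_text = rec$raw_text)
  if (a$doc_label != as.integer(rec$doc_label)) {
    ade_stop(
      "line %d: article '%s' stores doc_label %s but its sentences imply %d",
      line, rec$doc_id, rec$doc_label, a$doc_label)
  }
  a
}

#' Read a JSON-lines article corpus
#'
#' One JSON object per line; every record must carry
#' `schema_version = "1.0"`. All data-model invariants are enforced; a
#' malformed record raises an error naming the line, an invariant violation
#' an error naming the article and rule.
#'
#' @param path Path to a JSON-lines corpus file (UTF-8).
#' @param schema_version Expected schema version (currently `"1.0"`).
#' @return An `ade_corpus`.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, schema_version = CORPUS_SCHEMA_VERSION) {
  if (!file.exists(path)) ade_stop("corpus file not found: %s", path)
  stopifnot(identical(schema_version, CORPUS_SCHEMA_VERSION))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), class = "ade_corpus"))
  arts <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) ade_stop("line %d: malformed JSON (%s)",
                                   i, conditionMessage(e))
    )
    record_to_article(rec, i)
  })
  corpus(arts)
}

article_to_record <- function(a) {
  list(
    schema_version = CORPUS_SCHEMA_VERSION,
    doc_id = a$doc_id,
    raw_text = a$raw_text,
    doc_label = a$doc_label,
    sentences = lapply(a$sentences, function(s) {
      list(
        sent_id = s$sent_id,
        text = s$text,
        sent_label = s$sent_label,
        criterion = s$criterion,
        spans = lapply(seq_len(nrow(s$spans)), function(i) {
          z <- s$spans[i, ]
          list(start = z$start, end = z$end, etype = z$etype,
               surface = z$surface,
               standard = if (is.na(z$standard)) NULL else z$standard)
        })
      )
    })
  )
}

#' Write a corpus as JSON lines
#'
#' Inverse of [read_corpus()]: reading a written corpus reproduces it
#' field for field.
#'
#' @param articles An `ade_corpus` (or plain list of articles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(articles, path) {
  validate_corpus(articles)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (a in articles) {
    json <- jsonlite::toJSON(article_to_record(a), auto_unbox = TRUE,
                             null = "null", digits = NA)
    writeLines(json, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a surface-form dictionary
#'
#' Dictionaries map entity surface forms to standard names (many-to-one),
#' stand-ins for large disease/drug terminologies such as the MANBYO and
#' HYAKUYAKU resources. Format: 2-column TSV (`surface TAB standard`), no
#' header, UTF-8. Duplicate surfaces keep the first occurrence; a warning is
#' emitted when the dropped row disagrees.
#'
#' @param path Path to a TSV file.
#' @param etype `"disease"` or `"drug"`.
#' @return An object of class `ade_dictionary`: `etype` plus `entries`, a
#'   named character vector (names = surfaces, values = standard names).
#' @export
read_dictionary <- function(path, etype = c("disease", "drug")) {
  etype <- match.arg(etype)
  if (!file.exists(path)) ade_stop("dictionary file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2L)) {
    ade_stop("dictionary %s: line %d has %d column(s), expected 2",
             path, which(nc != 2L)[1], nc[nc != 2L][1])
  }
  surfaces <- vapply(parts, `[[`, character(1), 1L)
  standards <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(surfaces)) || any(!nzchar(standards))) {
    ade_stop("dictionary %s: empty surface or standard at line %d", path,
             which(!nzchar(surfaces) | !nzchar(standards))[1])
  }
  dup <- duplicated(surfaces)
  if (any(dup)) {
    warning(sprintf(
      "dictionary %s: %d duplicate surface form(s); keeping first occurrence",
      path, sum(dup)), call. = FALSE)
  }
  dictionary(etype, surfaces[!dup], standards[!dup])
}

#' Construct a dictionary in memory
#'
#' @param etype `"disease"` or `"drug"`.
#' @param surfaces Character vector of surface forms (unique, non-empty).
#' @param standards Standard names, one per surface.
#' @return An `ade_dictionary`.
#' @export
dictionary <- function(etype, surfaces, standards) {
  stopifnot(length(surfaces) == length(standards),
            !anyDuplicated(surfaces), all(nzchar(surfaces)),
            all(nzchar(standards)))
  entries <- stats::setNames(as.character(standards), as.character(surfaces))
  structure(list(etype = match.arg(etype, c("disease", "drug")),
                 entries = entries),
            class = "ade_dictionary")
}

#' Write a dictionary as 2-column TSV
#'
#' @param dict An `ade_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  writeLines(paste(names(dict$entries), dict$entries, sep = "\t"),
             con <- file(path, open = "wb"), useBytes = TRUE)
  close(con)
  invisible(path)
}

#' @export
print.ade_dictionary <- function(x, ...) {
  cat(sprintf("<ade_dictionary> %s: %d surfaces, %d standard names\n",
              x$etype, length(x$entries), length(unique(x$entries))))
  invisible(x)
}
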