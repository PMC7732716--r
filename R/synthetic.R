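# Seeded synthetic corpora and toy dictionaries with the statistical
# structure of an annotated case-report corpus: ~58.9% ADE-containing
# documents, one contiguous run of ADE-suggesting sentences per positive
# document with mean length 3.9 (SD 2.7), a background of non-ADE sentences
# with mean count 48.2 (SD 72.1, clamped to >= 1), entity mentions drawn as
# dictionary surface variants with optional per-character noise, and cue
# phrases marking the positive class at a configurable strength.
#
# Text is a whitespace-tokenizable pseudo-language over closed syllable
# inventories. Word classes use disjoint initial letters so disease
# surfaces, drug surfaces, filler words and cue words can never collide:
#   disease d/g/p/z, drug b/k/m/r, filler s/t/n/h, cue w/y.
# An optional Japanese-character mode transliterates every syllable to a
# katakana character and exercises the script-aware preprocessing rules.

SYLL_DISEASE <- c("da", "de", "do", "ga", "gi", "gu", "pa", "pe", "po",
                  "za", "ze", "zo")
SYLL_DRUG <- c("ba", "bi", "bu", "ke", "ko", "ku", "ma", "me", "mo",
               "ra", "ri", "ru")
SYLL_FILLER <- c("sa", "se", "si", "so", "su", "ta", "te", "ti", "to",
                 "tu", "na", "ne", "ni", "no", "nu", "ha", "he", "hi",
                 "ho", "hu")
CUE_WORDS <- c("wayawo", "weyuwa", "wiyowe", "woyawi", "yawayu", "yowiwe",
               "yuwewo", "wayuyo")

# one katakana character per syllable (stable lookup for Japanese mode)
SYLL_KANA <- stats::setNames(
  strsplit(paste0(
    "ダデドガギグパペポザゼゾ",
    "バビブケコクマメモラリル",
    "サセシソスタテチトツナネ",
    "ニノヌハヘヒホフ",
    "ワヱヰヲヤヨユウ"),
    "")[[1]],
  c(SYLL_DISEASE, SYLL_DRUG, SYLL_FILLER,
    "wa", "we", "wi", "wo", "ya", "yo", "yu", "wu"))

translit_kana <- function(word) {
  syl <- substring(word, seq(1, nchar(word), 2), seq(2, nchar(word), 2))
  kana <- SYLL_KANA[syl]
  kana[is.na(kana)] <- "ア"
  paste(kana, collapse = "")
}

#' Generator configuration
#'
#' Defaults encode the corpus conditions the generator emulates: 58.9%
#' positive documents, ADE-suggesting runs of mean 3.9 (SD 2.7) sentences,
#' 48.2 (SD 72.1) non-ADE sentences per article, and criterion A vs B mixed
#' at 3.5 : 0.4.
#'
#' @param n_docs Number of articles.
#' @param positive_rate Probability a document is ADE containing.
#' @param ade_run_mean,ade_run_sd Length distribution of the contiguous
#'   ADE-suggesting sentence run (normal, rounded, clamped to `>= 1`).
#' @param nonade_sent_mean,nonade_sent_sd Count distribution of non-ADE
#'   sentences per article (same clamped rounding).
#' @param n_diseases,n_drugs Number of canonical entity names per type.
#' @param variant_noise Per-character substitution probability applied to
#'   mention surfaces (surface-form variation beyond the dictionary).
#' @param cue_strength Probability an ADE-suggesting sentence carries a cue
#'   phrase; the lexical signal separating the classes.
#' @param bg_style_rate Background sentences of ADE-containing documents
#'   carry a single cue-style token with probability
#'   `bg_style_rate * cue_strength`, emulating case-report phrasing that
#'   pervades positive articles beyond the annotated ADE run (the source of
#'   sentence-level false positives in real corpora: general statements
#'   worded like actual cases).
#' @param criterion_a_rate Probability a run sentence is criterion A rather
#'   than B (default 3.5 / 3.9).
#' @param bg_disease_rate,bg_drug_rate Probability a background sentence
#'   mentions a disease / drug (general-statement distractors).
#' @param filler_vocab_size Closed filler vocabulary size.
#' @param equalize_classes When `TRUE`, ADE-run sentences are generated
#'   from the background template so the two classes are distributionally
#'   identical (null-signal control; combine with `cue_strength = 0`).
#' @param japanese_mode Transliterate every word to katakana.
#' @param seed Integer seed; same config and seed give identical output.
#' @return A `ade_generator_config` list.
#' @export
generator_config <- function(n_docs = 100L, positive_rate = 0.589,
                             ade_run_mean = 3.9, ade_run_sd = 2.7,
                             nonade_sent_mean = 48.2, nonade_sent_sd = 72.1,
                             n_diseases = 30L, n_drugs = 30L,
                             variant_noise = 0.05, cue_strength = 0.9,
                             criterion_a_rate = 3.5 / 3.9,
                             bg_style_rate = 0.3,
                             bg_disease_rate = 0.2, bg_drug_rate = 0.2,
                             filler_vocab_size = 300L,
                             equalize_classes = FALSE,
                             japanese_mode = FALSE, seed = 1L) {
  cfg <- list(n_docs = as.integer(n_docs), positive_rate = positive_rate,
              ade_run_mean = ade_run_mean, ade_run_sd = ade_run_sd,
              nonade_sent_mean = nonade_sent_mean,
              nonade_sent_sd = nonade_sent_sd,
              n_diseases = as.integer(n_diseases),
              n_drugs = as.integer(n_drugs),
              variant_noise = variant_noise, cue_strength = cue_strength,
              criterion_a_rate = criterion_a_rate,
              bg_style_rate = bg_style_rate,
              bg_disease_rate = bg_disease_rate,
              bg_drug_rate = bg_drug_rate,
              filler_vocab_size = as.integer(filler_vocab_size),
              equalize_classes = isTRUE(equalize_classes),
              japanese_mode = isTRUE(japanese_mode),
              seed = as.integer(seed))
  probs <- c("positive_rate", "variant_noise", "cue_strength",
             "criterion_a_rate", "bg_style_rate", "bg_disease_rate",
             "bg_drug_rate")
  stopifnot(all(unlist(cfg[probs]) >= 0), all(unlist(cfg[probs]) <= 1),
            cfg$ade_run_mean > 0, cfg$nonade_sent_mean > 0,
            cfg$n_docs >= 1L)
  structure(cfg, class = "ade_generator_config")
}

sample_words <- function(n, inventory, min_syll = 3L, max_syll = 5L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    words <- vapply(seq_len(need), function(i) {
      paste(sample(inventory, sample(min_syll:max_syll, 1L),
                   replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, words))
  }
  out[seq_len(n)]
}

make_variants <- function(canonical, inventory) {
  n_var <- sample(1:3, 1L)
  vars <- character(0)
  for (i in seq_len(n_var)) {
    syl <- substring(canonical, seq(1, nchar(canonical), 2),
                     seq(2, nchar(canonical), 2))
    pos <- sample(length(syl), 1L)
    syl[pos] <- sample(setdiff(inventory, syl[pos]), 1L)
    vars <- c(vars, paste(syl, collapse = ""))
  }
  unique(setdiff(vars, canonical))
}

#' Generate toy disease and drug dictionaries
#'
#' Canonical names are synthesized from closed, type-disjoint syllable
#' inventories; each canonical maps to itself plus 1-3 surface variants
#' (single-syllable substitutions, so every variant keeps similarity well
#' above the 0.3 normalization threshold). Disease and drug surface sets
#' are disjoint by construction.
#'
#' @param config An `ade_generator_config`.
#' @return List with `disease` and `drug` `ade_dictionary` objects.
#' @export
generate_dictionaries <- function(config) {
  withr::with_seed(config$seed, {
    build <- function(n, inventory, etype) {
      canon <- sample_words(n, inventory)
      surfaces <- character(0); standards <- character(0)
      for (cn in canon) {
        vars <- unique(c(cn, make_variants(cn, inventory)))
        vars <- setdiff(vars, surfaces)
        surfaces <- c(surfaces, vars)
        standards <- c(standards, rep(cn, length(vars)))
      }
      if (config$japanese_mode) {
        surfaces <- vapply(surfaces, translit_kana, character(1),
                           USE.NAMES = FALSE)
        standards <- vapply(standards, translit_kana, character(1),
                            USE.NAMES = FALSE)
        keep <- !duplicated(surfaces)
        surfaces <- surfaces[keep]; standards <- standards[keep]
      }
      dictionary(etype, surfaces, standards)
    }
    list(disease = build(config$n_diseases, SYLL_DISEASE, "disease"),
         drug = build(config$n_drugs, SYLL_DRUG, "drug"))
  })
}

clamped_count <- function(n, mean, sd) {
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

noise_surface <- function(surface, rate, japanese) {
  if (rate <= 0) return(surface)
  ch <- chars_of(surface)
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    pool <- if (japanese) unname(SYLL_KANA) else letters
    ch[hit] <- sample(pool, sum(hit), replace = TRUE)
  }
  paste(ch, collapse = "")
}

# A sentence under construction: filler/cue tokens plus mention tokens with
# their entity type recorded; realized into text + spans by realize_sentence.
new_tokens <- function() list(tok = character(0), etype = character(0))

push <- function(tk, words, etype = NA_character_) {
  tk$tok <- c(tk$tok, words)
  tk$etype <- c(tk$etype, rep(etype, length(words)))
  tk
}

realize_sentence <- function(tk, sent_label, criterion, config) {
  tok <- tk$tok
  if (config$japanese_mode) {
    plain <- is.na(tk$etype)
    tok[plain] <- vapply(tok[plain], translit_kana, character(1),
                         USE.NAMES = FALSE)
    # mention tokens were transliterated when drawn from the dictionary
  }
  is_mention <- !is.na(tk$etype)
  if (any(is_mention) && config$variant_noise > 0) {
    tok[is_mention] <- vapply(tok[is_mention], noise_surface, character(1),
                              rate = config$variant_noise,
                              japanese = config$japanese_mode,
                              USE.NAMES = FALSE)
  }
  text <- paste0(paste(tok, collapse = " "), "。")
  if (any(is_mention)) {
    starts <- cumsum(c(0L, nchar(tok) + 1L))[seq_along(tok)]
    idx <- which(is_mention)
    spans <- entity_spans(starts[idx], starts[idx] + nchar(tok[idx]),
                         tk$etype[idx], tok[idx])
    spans <- spans[order(spans$start), , drop = FALSE]
  } else spans <- entity_spans()
  sentence(text, sent_label = sent_label, criterion = criterion,
           spans = spans)
}

draw_mention <- function(variants_by_std) {
  std <- sample(names(variants_by_std), 1L)
  sample(variants_by_std[[std]], 1L)
}

#' Generate a seeded synthetic corpus
#'
#' See [generator_config()] for the emulated structure. Every positive
#' document carries one contiguous run of ADE-suggesting sentences
#' (criterion A: drug mention then disease mention, with a cue phrase at
#' `cue_strength`; criterion B: explicit statement with a disease mention
#' and cue). Background sentences are filler text with occasional entity
#' mentions (general-statement distractors). Gold spans, sentence labels,
#' criterion tags and document labels are emitted, and the output passes
#' [validate_corpus()].
#'
#' @param config An `ade_generator_config`.
#' @param dictionaries Output of [generate_dictionaries()].
#' @return An `ade_corpus`.
#' @export
generate_corpus <- function(config, dictionaries) {
  variants <- lapply(dictionaries[c("disease", "drug")], function(d) {
    split(names(d$entries), d$entries)
  })
  withr::with_seed(config$seed, {
    fillers <- sample_words(config$filler_vocab_size, SYLL_FILLER,
                            min_syll = 2L, max_syll = 4L)
    filler_run <- function(n) sample(fillers, n, replace = TRUE)

    bg_sentence <- function(style = FALSE) {
      tk <- push(new_tokens(), filler_run(sample(5:12, 1L)))
      if (stats::runif(1) < config$bg_disease_rate) {
        tk <- insert_mention(tk, draw_mention(variants$disease), "disease")
      }
      if (stats::runif(1) < config$bg_drug_rate) {
        tk <- insert_mention(tk, draw_mention(variants$drug), "drug")
      }
      if (style &&
          stats::runif(1) < config$bg_style_rate * config$cue_strength) {
        tk <- insert_mention(tk, sample(CUE_WORDS, 1L))
      }
      tk
    }
    insert_mention <- function(tk, word, etype = NA_character_) {
      pos <- sample(0:length(tk$tok), 1L)
      tk$tok <- append(tk$tok, word, after = pos)
      tk$etype <- append(tk$etype, etype, after = pos)
      tk
    }
    cue_phrase <- function() sample(CUE_WORDS, 2L)
    ade_sentence_tokens <- function(criterion) {
      tk <- push(new_tokens(), filler_run(sample(1:3, 1L)))
      if (criterion == "A") {
        tk <- push(tk, draw_mention(variants$drug), "drug")
        tk <- push(tk, filler_run(sample(1:2, 1L)))
        tk <- push(tk, draw_mention(variants$disease), "disease")
      } else {
        tk <- push(tk, draw_mention(variants$disease), "disease")
      }
      if (stats::runif(1) < config$cue_strength) {
        tk <- push(tk, cue_phrase())
      }
      push(tk, filler_run(sample(2:5, 1L)))
    }

    arts <- vector("list", config$n_docs)
    positives <- stats::rbinom(config$n_docs, 1L, config$positive_rate)
    # both classes must occur for the corpus to be usable downstream
    if (config$n_docs >= 2L) {
      if (all(positives == 1L)) positives[1L] <- 0L
      if (all(positives == 0L)) positives[1L] <- 1L
    }
    for (d in seq_len(config$n_docs)) {
      n_bg <- clamped_count(1L, config$nonade_sent_mean,
                            config$nonade_sent_sd)
      styled <- positives[d] == 1L && !config$equalize_classes
      sents <- lapply(seq_len(n_bg), function(i) {
        realize_sentence(bg_sentence(style = styled), 0L, "none", config)
      })
      if (positives[d] == 1L) {
        run_len <- clamped_count(1L, config$ade_run_mean, config$ade_run_sd)
        crits <- ifelse(stats::runif(run_len) < config$criterion_a_rate,
                        "A", "B")
        run <- lapply(crits, function(cr) {
          tk <- if (config$equalize_classes) bg_sentence()
                else ade_sentence_tokens(cr)
          realize_sentence(tk, 1L, cr, config)
        })
        at <- sample(0:n_bg, 1L)
        sents <- append(sents, run, after = at)
      }
      arts[[d]] <- article(sprintf("doc%05d", d), sents)
    }
    corpus(arts)
  })
}

#' Simulate OCR noise on an article
#'
#' Characters are independently perturbed at `char_error_rate`: half of the
#' hits are deletions, half substitutions (replacement drawn from the
#' generator's character pool). Gold span offsets are remapped; a span
#' whose characters are all deleted is dropped; surviving spans keep
#' `surface == text slice`. Labels are unchanged.
#'
#' @param article An `ade_article`.
#' @param char_error_rate Rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return The perturbed article.
#' @export
perturb_ocr <- function(article, char_error_rate, seed = 1L) {
  stopifnot(char_error_rate >= 0, char_error_rate < 1)
  if (char_error_rate == 0) return(article)
  withr::with_seed(seed, {
    sents <- lapply(article$sentences, function(s) {
      ch <- chars_of(s$text)
      n <- length(ch)
      u <- stats::runif(n)
      hit <- u < char_error_rate
      del <- hit & (u < char_error_rate / 2)
      sub <- hit & !del
      pool <- c(letters, unname(SYLL_KANA))
      ch[sub] <- sample(pool, sum(sub), replace = TRUE)
      keep <- !del
      if (!any(keep)) keep[1L] <- TRUE  # sentences must stay non-empty
      new_text <- paste(ch[keep], collapse = "")
      # survivors before position i (0-based prefix counts)
      surv_before <- c(0L, cumsum(keep))
      sp <- s$spans
      if (nrow(sp)) {
        new_start <- surv_before[sp$start + 1L]
        new_end <- surv_before[sp$end + 1L]
        alive <- new_end > new_start
        sp <- sp[alive, , drop = FALSE]
        if (nrow(sp)) {
          sp$start <- new_start[alive]
          sp$end <- new_end[alive]
          sp$surface <- substring(new_text, sp$start + 1L, sp$end)
        }
      }
      sentence(new_text, s$sent_label, s$criterion, spans = sp)
    })
    article(article$doc_id, sents)
  })
}
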