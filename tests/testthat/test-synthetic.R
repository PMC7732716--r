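test_that("generation is deterministic and passes corpus validation", {
  cfg <- small_config(n_docs = 15, seed = 12)
  d1 <- generate_dictionaries(cfg)
  d2 <- generate_dictionaries(cfg)
  expect_identical(d1, d2)
  c1 <- generate_corpus(cfg, d1)
  c2 <- generate_corpus(cfg, d1)
  expect_identical(c1, c2)
  expect_silent(validate_corpus(c1))
  # several random configurations all produce valid corpora
  withr::with_seed(61, {
    for (i in 1:8) {
      cfg_i <- generator_config(
        n_docs = sample(3:10, 1), nonade_sent_mean = sample(2:8, 1),
        nonade_sent_sd = runif(1, 0.5, 3), positive_rate = runif(1, 0.2, 0.8),
        cue_strength = runif(1), variant_noise = runif(1, 0, 0.2),
        n_diseases = sample(3:10, 1), n_drugs = sample(3:10, 1),
        seed = sample(1e6, 1))
      expect_silent(validate_corpus(
        generate_corpus(cfg_i, generate_dictionaries(cfg_i))))
    }
  })
})

test_that("the positive-document fraction tracks the configured rate", {
  cfg <- generator_config(n_docs = 1000, nonade_sent_mean = 3,
                          nonade_sent_sd = 1, seed = 7)
  corp <- generate_corpus(cfg, generate_dictionaries(cfg))
  frac <- mean(vapply(corp, function(a) a$doc_label, integer(1)))
  expect_lt(abs(frac - 0.589), 0.05)
})

test_that("positive documents carry one contiguous ADE-suggesting run", {
  gen <- small_corpus(n_docs = 40, seed = 44)
  for (a in gen$corpus) {
    labs <- vapply(a$sentences, function(s) s$sent_label, integer(1))
    if (a$doc_label == 1L) {
      pos <- which(labs == 1L)
      expect_gte(length(pos), 1L)
      expect_identical(pos, seq(min(pos), max(pos)))
      crits <- vapply(a$sentences[pos], function(s) s$criterion, character(1))
      expect_true(all(crits %in% c("A", "B")))
    } else {
      expect_identical(sum(labs), 0L)
    }
  }
})

test_that("dictionary variants stay similar to their canonical names", {
  cfg <- small_config(n_docs = 2, seed = 3)
  dicts <- generate_dictionaries(cfg)
  for (d in dicts) {
    sims <- similarity(names(d$entries), unname(d$entries))
    expect_true(all(sims > 0.3))
  }
  # disease and drug surface sets are disjoint
  expect_length(intersect(names(dicts$disease$entries),
                          names(dicts$drug$entries)), 0L)
})

test_that("OCR perturbation respects its rate and preserves invariants", {
  gen <- small_corpus(n_docs = 3, seed = 5)
  a <- gen$corpus[[1]]
  expect_identical(perturb_ocr(a, 0), a)
  pert <- perturb_ocr(a, 0.2, seed = 5)
  expect_identical(pert$doc_label, a$doc_label)
  expect_silent(adescreen:::validate_article(pert))
  # expected number of edited positions ~ Binomial(n, rate) over many seeds
  txt <- "abcdefghij"
  art <- article("x", list(sentence(txt)))
  edits <- vapply(1:300, function(s) {
    lev_dp(txt, perturb_ocr(art, 0.3, seed = s)$sentences[[1]]$text)
  }, numeric(1))
  expect_lt(abs(mean(edits) - 3), 0.6)
})

test_that("raw text round-trips through the sentence splitter in both modes", {
  for (jp in c(FALSE, TRUE)) {
    cfg <- generator_config(n_docs = 4, nonade_sent_mean = 5,
                            nonade_sent_sd = 2, japanese_mode = jp,
                            seed = 20)
    corp <- generate_corpus(cfg, generate_dictionaries(cfg))
    for (a in corp) {
      texts <- vapply(a$sentences, function(s) s$text, character(1))
      expect_identical(split_sentences(a$raw_text), unname(texts))
    }
  }
})

test_that("classification difficulty rises as the cue signal weakens", {
  f1_at <- function(cue, seed) {
    cfg <- generator_config(n_docs = 50, nonade_sent_mean = 8,
                            nonade_sent_sd = 3, cue_strength = cue,
                            equalize_classes = (cue == 0), seed = seed)
    dicts <- generate_dictionaries(cfg)
    corp <- generate_corpus(cfg, dicts)
    cross_validate(corp, "document", dicts, k = 5, seed = seed)$mean_f1
  }
  means <- vapply(c(0, 0.5, 0.9), function(cue) {
    mean(vapply(1:3, function(s) f1_at(cue, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= -0.02))
  expect_gt(means[3], means[1])
})
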