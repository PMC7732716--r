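make_split <- function(gen, n_train) {
  corp <- normalize_corpus(gen$corpus, gen$dicts)
  train <- structure(corp[seq_len(n_train)], class = "ade_corpus")
  held <- structure(corp[(n_train + 1):length(corp)], class = "ade_corpus")
  vocab <- fit_vocabulary(unlist(lapply(train, function(a) {
    vapply(a$sentences, function(s) s$text, character(1))
  })))
  list(train = train, held = held, vocab = vocab)
}

test_that("the document classifier recovers a strong cue signal held-out", {
  cfg <- generator_config(n_docs = 150, nonade_sent_mean = 20,
                          nonade_sent_sd = 8, seed = 42)
  dicts <- generate_dictionaries(cfg)
  gen <- list(corpus = generate_corpus(cfg, dicts), dicts = dicts)
  sp <- make_split(gen, 100)
  m <- train_document_model(sp$train, sp$vocab, seed = 42)
  res <- screen(sp$held, m, m, mode = "flat")
  truth <- vapply(sp$held, function(a) a$doc_label, integer(1))
  tp <- sum(res$documents$pred == 1 & truth == 1)
  f1 <- prf(tp, sum(res$documents$pred == 1 & truth == 0),
            sum(res$documents$pred == 0 & truth == 1))[["f1"]]
  expect_gte(f1, 0.9)
  # determinism: identical seeds and corpus give identical weights
  m2 <- train_document_model(sp$train, sp$vocab, seed = 42)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$intercept, m2$intercept)
})

test_that("permuted labels collapse to the always-positive baseline", {
  gen <- small_corpus(n_docs = 100, seed = 13)
  corp <- normalize_corpus(gen$corpus, gen$dicts)
  permuted <- withr::with_seed(99, {
    labs <- vapply(corp, function(a) a$doc_label, integer(1))
    new_labs <- sample(labs)
    structure(lapply(seq_along(corp), function(i) {
      a <- corp[[i]]
      # relabel without touching text: flip sentence labels to match
      a$sentences <- lapply(a$sentences, function(s) {
        sentence(s$text, 0L, "none", s$spans)
      })
      if (new_labs[i] == 1L) {
        s1 <- a$sentences[[1]]
        a$sentences[[1]] <- sentence(s1$text, 1L, "A", s1$spans)
      }
      article(a$doc_id, a$sentences)
    }), class = "ade_corpus")
  })
  sp <- list(train = structure(permuted[1:70], class = "ade_corpus"),
             held = structure(permuted[71:100], class = "ade_corpus"))
  vocab <- fit_vocabulary(unlist(lapply(sp$train, function(a) {
    vapply(a$sentences, function(s) s$text, character(1))
  })))
  m <- train_document_model(sp$train, vocab, seed = 1)
  res <- screen(sp$held, m, m, mode = "flat")
  truth <- vapply(sp$held, function(a) a$doc_label, integer(1))
  f1 <- prf(sum(res$documents$pred == 1 & truth == 1),
            sum(res$documents$pred == 1 & truth == 0),
            sum(res$documents$pred == 0 & truth == 1))[["f1"]]
  p <- mean(truth)
  baseline <- 2 * p / (p + 1)   # predict everything positive
  expect_lt(abs(f1 - baseline), 0.1)
})

test_that("sentence training uses exactly the sentences of positive articles", {
  gen <- small_corpus(n_docs = 40, seed = 6)
  corp <- normalize_corpus(gen$corpus, gen$dicts)
  vocab <- fit_vocabulary(unlist(lapply(corp, function(a) {
    vapply(a$sentences, function(s) s$text, character(1))
  })))
  m <- train_sentence_model(corp, vocab, seed = 6)
  expected_n <- sum(vapply(corp, function(a) {
    if (a$doc_label == 1L) length(a$sentences) else 0L
  }, integer(1)))
  expect_identical(m$meta$n_train, expected_n)
  # all-negative training set is an error
  negs <- Filter(function(a) a$doc_label == 0L, corp)
  expect_error(train_sentence_model(negs, vocab), "no ADE-containing")
  # single-class document training set is an error
  expect_error(train_document_model(
    structure(negs, class = "ade_corpus"), vocab), "single class")
})

test_that("pipeline mode gates sentence predictions on the document decision", {
  gen <- small_corpus(n_docs = 60, seed = 17)
  sp <- make_split(gen, 40)
  dm <- train_document_model(sp$train, sp$vocab)
  sm <- train_sentence_model(sp$train, sp$vocab)
  flat <- screen(sp$held, dm, sm, mode = "flat")
  pipe <- screen(sp$held, dm, sm, mode = "pipeline")
  n_sent <- vapply(sp$held, function(a) length(a$sentences), integer(1))
  expect_identical(nrow(flat$sentences), sum(n_sent))
  pos_docs <- flat$documents$doc_id[flat$documents$pred == 1]
  expect_setequal(unique(pipe$sentences$doc_id), pos_docs)
  # where both modes emit predictions, probabilities are identical
  key <- paste(pipe$sentences$doc_id, pipe$sentences$sent_id)
  flat_key <- paste(flat$sentences$doc_id, flat$sentences$sent_id)
  expect_identical(pipe$sentences$prob,
                   flat$sentences$prob[match(key, flat_key)])
})

test_that("coefficient export round-trips probabilities", {
  gen <- small_corpus(n_docs = 40, seed = 23)
  sp <- make_split(gen, 30)
  m <- train_document_model(sp$train, sp$vocab)
  cf <- coef(m)
  expect_identical(cf$weight, cf$weight[order(-abs(cf$weight), cf$feature)])
  rebuilt <- classifier_from_coefficients(cf, template = m)
  r1 <- screen(sp$held, m, m, mode = "flat")
  r2 <- screen(sp$held, rebuilt, rebuilt, mode = "flat")
  expect_equal(r1$documents$prob, r2$documents$prob, tolerance = 1e-12)
  # JSON serialization round trip
  f <- withr::local_tempfile()
  write_classifier(m, f)
  m3 <- read_classifier(f)
  r3 <- screen(sp$held, m3, m3, mode = "flat")
  expect_equal(r1$documents$prob, r3$documents$prob, tolerance = 1e-12)
})

test_that("adding the top positive-weight feature never lowers the probability", {
  gen <- small_corpus(n_docs = 40, seed = 29)
  sp <- make_split(gen, 30)
  m <- train_document_model(sp$train, sp$vocab)
  cf <- coef(m)
  top <- cf$feature[cf$weight == max(cf$weight)][1]
  X <- Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                            dims = c(1, 1),
                            dimnames = list(NULL, top))
  p1 <- adescreen:::classifier_scores(m, X)
  X2 <- X; X2[1, 1] <- 2
  expect_gte(adescreen:::classifier_scores(m, X2), p1)
})
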