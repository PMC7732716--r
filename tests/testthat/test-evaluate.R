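test_that("prf follows its definition with zero-denominator conventions", {
  expect_equal(prf(5, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(prf(3, 1, 2),
               c(precision = 0.75, recall = 0.6,
                 f1 = 2 * 0.75 * 0.6 / 1.35))
  expect_equal(prf(0, 0, 0), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(0, 3, 0)[["precision"]], 0)
  withr::with_seed(3, {
    for (i in 1:300) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      m <- prf(tp, fp, fn)
      pr <- if (tp + fp) tp / (tp + fp) else 0
      rc <- if (tp + fn) tp / (tp + fn) else 0
      expect_equal(m[["precision"]], pr)
      expect_equal(m[["recall"]], rc)
      expect_equal(m[["f1"]],
                   if (pr + rc) 2 * pr * rc / (pr + rc) else 0)
    }
  })
})

test_that("stratified folds keep the label proportion within one document", {
  labs <- c(rep(1L, 6), rep(0L, 4))
  # the minority class has fewer than k members: flagged, but the split
  # still balances sizes and positives
  expect_warning(f <- stratified_kfold(labs, k = 5, seed = 2), "fewer than")
  expect_true(all(table(f) == 2))
  pos_per_fold <- tapply(labs, f, sum)
  expect_true(all(pos_per_fold >= 1 & pos_per_fold <= 2))
  expect_identical(f, suppressWarnings(stratified_kfold(labs, 5, seed = 2)))
  expect_false(identical(
    f, suppressWarnings(stratified_kfold(labs, 5, seed = 3))))

  f2 <- stratified_kfold(c(1L, 1L, 0L, 0L), k = 2, seed = 1)
  expect_true(all(tapply(c(1L, 1L, 0L, 0L), f2, sum) == 1))
  expect_error(stratified_kfold(rep(1L, 10), k = 5), "both classes")

  # general proportion invariant on generated corpora
  gen <- small_corpus(n_docs = 57, seed = 31)
  fa <- stratified_kfold(gen$corpus, k = 5, seed = 31)
  labs2 <- vapply(gen$corpus, function(a) a$doc_label, integer(1))
  p_global <- mean(labs2)
  for (k in 1:5) {
    expect_lte(abs(sum(labs2[fa == k]) - sum(fa == k) * p_global), 1)
  }
})

test_that("the precision-recall curve matches brute-force recomputation", {
  # perfectly separated scores reach the (1, 1) corner
  curve <- pr_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_true(any(curve$precision == 1 & curve$recall == 1))
  # constant scores give a single all-positive point
  curve2 <- pr_curve(rep(0.5, 4), c(1, 0, 1, 1))
  expect_identical(nrow(curve2), 1L)
  expect_equal(curve2$recall, 1)
  expect_equal(curve2$precision, 0.75)
  expect_error(pr_curve(c(0.1, 0.2), c(1, 1)), "both classes")
  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      scores <- round(runif(n), 2)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      curve <- pr_curve(scores, labels)
      expect_true(all(diff(curve$threshold) > 0))
      expect_true(all(diff(curve$recall) <= 0))
      for (j in seq_len(nrow(curve))) {
        ref <- pr_at_threshold(scores, labels, curve$threshold[j])
        expect_equal(curve$precision[j], ref[["precision"]])
        expect_equal(curve$recall[j], ref[["recall"]])
      }
    }
  })
})

test_that("Cohen's kappa matches the contingency-table oracle", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(cohen_kappa(c(1, 1), c(1, 1)), "undefined")
  expect_error(cohen_kappa(integer(0), integer(0)), "non-empty")
  withr::with_seed(53, {
    for (i in 1:200) {
      n <- sample(4:40, 1)
      a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
      if (mean(a == b) == 1 && length(unique(a)) == 1) next
      expect_equal(cohen_kappa(a, b), kappa_oracle(a, b))
      expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
    }
  })
})

test_that("cross-validation accounts for every test sentence and uses population SD", {
  gen <- small_corpus(n_docs = 40, seed = 11)
  cv <- cross_validate(gen$corpus, "sentence", gen$dicts, k = 5, seed = 11)
  n_sent <- vapply(gen$corpus, function(a) length(a$sentences), integer(1))
  for (k in 1:5) {
    expect_identical(cv$n_eval[k], sum(n_sent[cv$folds == k]))
  }
  expect_equal(cv$sd_f1, sqrt(mean((cv$fold_f1 - mean(cv$fold_f1))^2)))
  expect_length(cv$fold_f1, 5L)
  expect_identical(cv$seed, 11)
  # determinism end to end
  cv2 <- cross_validate(gen$corpus, "sentence", gen$dicts, k = 5, seed = 11)
  expect_identical(cv$fold_f1, cv2$fold_f1)
})

test_that("ablation removes groups against a fixed baseline", {
  gen <- small_corpus(n_docs = 40, seed = 19)
  rep_ <- ablation(gen$corpus, "document",
                   groups = c("dummy", "word_tokens"),
                   dictionaries = gen$dicts, k = 5, seed = 19)
  expect_identical(rep_$delta_f1[rep_$group == "dummy"], 0)
  expect_lt(rep_$delta_f1[rep_$group == "word_tokens"], 0)
  expect_error(
    ablation(gen$corpus, "document", groups = "ctx_word_tokens",
             dictionaries = gen$dicts, k = 5, seed = 19),
    "not valid")
  expect_error(
    ablation(gen$corpus, "document", groups = "no_such_group",
             dictionaries = gen$dicts, k = 5, seed = 19),
    "not valid")
})

test_that("learning curve at fraction 1 reproduces cross-validation exactly", {
  gen <- small_corpus(n_docs = 40, seed = 27)
  cv <- cross_validate(gen$corpus, "document", gen$dicts, k = 5, seed = 27)
  lc <- learning_curve(gen$corpus, "document", fractions = c(0.5, 1.0),
                       dictionaries = gen$dicts, k = 5, seed = 27)
  expect_identical(lc$validation_f1[lc$fraction == 1], cv$mean_f1)
  expect_identical(nrow(lc), 2L)
})
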