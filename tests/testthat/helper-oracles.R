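# Independent brute-force oracles (kept deliberately naive and separate from
# the implementation paths they check).

# Levenshtein distance by textbook dynamic programming.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

sim_oracle <- function(a, b) 1 - lev_dp(a, b) / max(nchar(a), nchar(b))

# Precision/recall at one threshold by direct counting.
pr_at_threshold <- function(scores, labels, t) {
  pred <- scores >= t
  tp <- sum(pred & labels == 1)
  c(precision = if (sum(pred)) tp / sum(pred) else 0,
    recall = tp / sum(labels == 1))
}

# Cohen's kappa from the explicit 2x2 contingency table.
kappa_oracle <- function(a, b) {
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

random_string <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Compact generator settings for fast module tests: the emulated label and
# run structure is kept, documents are short.
small_config <- function(n_docs = 60, seed = 1, ...) {
  generator_config(n_docs = n_docs, nonade_sent_mean = 10,
                   nonade_sent_sd = 5, seed = seed, ...)
}

small_corpus <- function(n_docs = 60, seed = 1, ...) {
  cfg <- small_config(n_docs, seed, ...)
  dicts <- generate_dictionaries(cfg)
  list(config = cfg, dicts = dicts,
       corpus = generate_corpus(cfg, dicts))
}

# Hand-built two-sentence article with one disease and one drug mention.
toy_article <- function(doc_id = "a1") {
  s1 <- sentence("aa bb dada cc。", sent_label = 1L, criterion = "A",
                 spans = entity_spans(6, 10, "disease", "dada"))
  s2 <- sentence("kuku dd。",
                 spans = entity_spans(0, 4, "drug", "kuku"))
  article(doc_id, list(s1, s2))
}
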