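# Shared fixtures: small corpora and embedding tables built in code.

tiny_corpus <- function(seed = 7L, n_notes = 60L, ...) {
  generate_corpus(generator_config(
    n_notes = n_notes, n_phenotypes = 3L, vocab_size = 120L,
    signal_tokens_per_phenotype = 4L, signal_rate = 0.3,
    sentences_per_note = c(3L, 6L), words_per_sentence = c(4L, 8L),
    label_prevalences = 0.35, singleton_rate = 0.02, seed = seed, ...))
}

# deterministic embedding table for a vocabulary (no CBOW training)
toy_embedding <- function(vocab, d = 8L, seed = 1L) {
  set.seed(seed)
  tab <- matrix(stats::runif(length(vocab$tokens) * d, -0.5, 0.5),
                ncol = d)
  tab[2, ] <- 0
  structure(tab, class = c("embedding_table", "matrix", "array"))
}

fast_train <- function(epochs = 5L, seed = 1L, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

# brute-force convolution oracle: explicit loops, no shared code path
conv_oracle <- function(x, weights, bias) {
  d <- ncol(x)
  l <- ncol(weights) / d
  T <- nrow(x) - l + 1
  out <- matrix(0, nrow = nrow(weights), ncol = T)
  for (m in seq_len(nrow(weights))) {
    for (t in seq_len(T)) {
      acc <- bias[m]
      for (j in seq_len(l)) {
        acc <- acc + sum(weights[m, ((j - 1) * d + 1):(j * d)] *
                           x[t + j - 1, ])
      }
      out[m, t] <- max(0, acc)
    }
  }
  out
}

# all-pairs AUROC oracle with half-credit for ties
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    for (n in neg)
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}
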