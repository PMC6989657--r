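test_that("class weights are reciprocal counts", {
  w <- compute_class_weights(c(pos = 100, neg = 300))
  expect_equal(unname(w), c(0.01, 1 / 300))
  expect_equal(unname(compute_class_weights(c(50, 50))), c(0.02, 0.02))
  counts <- c(10, 20, 40, 80)
  expect_true(all(diff(compute_class_weights(counts)) < 0))
  expect_error(compute_class_weights(c(5, 0)), ">= 1")
})

test_that("weighted cross-entropy has the stated closed forms", {
  expect_equal(weighted_cross_entropy(0.5, 1), log(2))
  expect_equal(weighted_cross_entropy(0.5, 0), log(2))
  p <- c(0.2, 0.7, 0.9)
  y <- c(0, 1, 1)
  expect_equal(weighted_cross_entropy(p, y),
               -(y * log(p) + (1 - y) * log(1 - p)))
  # doubling the positive weight doubles positive losses only
  w1 <- weighted_cross_entropy(p, y, weights = c(1, 1))
  w2 <- weighted_cross_entropy(p, y, weights = c(1, 2))
  expect_equal(w2[y == 1], 2 * w1[y == 1])
  expect_equal(w2[y == 0], w1[y == 0])
  # boundary probabilities are clamped, never infinite
  expect_true(is.finite(weighted_cross_entropy(0, 1)))
  expect_true(is.finite(weighted_cross_entropy(1, 0)))
})

train_fixture <- function(n_notes = 60L, seed = 7L) {
  corpus <- tiny_corpus(seed = seed, n_notes = n_notes)
  notes <- prepare_notes(corpus)
  list(corpus = corpus, notes = notes,
       tab = toy_embedding(notes$vocab, d = 8L),
       y = corpus$labels[, "phenotype_01"])
}

test_that("zero epochs leave the initialized parameters untouched", {
  fx <- train_fixture(n_notes = 10L)
  m <- cnn_model(fx$tab, filter_lengths = 1:2, n_maps = 3, seed = 2)
  fit <- fit_cnn(m, fx$notes, fx$y, config = fast_train(epochs = 0L))
  expect_identical(fit$model, m)
  expect_identical(nrow(fit$trace), 0L)
})

test_that("filter norms respect the max-norm constraint after training", {
  fx <- train_fixture()
  m <- cnn_model(fx$tab, filter_lengths = 1:3, n_maps = 8, seed = 2,
                 sentence_filter_lengths = c(1, 2), sentence_n_maps = 4)
  fit <- fit_cnn(m, fx$notes, fx$y,
                 config = fast_train(epochs = 3L, max_norm = 3))
  for (g in c(fit$model$word_filters, fit$model$sent_filters)) {
    norms <- sqrt(rowSums(g$W^2))
    expect_true(all(norms <= 3 + 1e-8))
  }
})

test_that("training is reproducible and produces a loss trace", {
  fx <- train_fixture(n_notes = 30L)
  run <- function() {
    m <- cnn_model(fx$tab, filter_lengths = 1:2, n_maps = 4, seed = 2)
    fit_cnn(m, fx$notes, fx$y, config = fast_train(epochs = 3L, seed = 11L))
  }
  a <- run()
  b <- run()
  expect_identical(a$model, b$model)
  expect_identical(a$trace, b$trace)
  expect_identical(nrow(a$trace), 3L)
  expect_true(all(is.finite(a$trace$train_loss)))
})

test_that("a separable one-token task is learned to low training loss", {
  # notes are labeled by the presence of a marker token; small batches give
  # the fixed 20-epoch budget enough optimizer steps at this sample size
  for (seed in 1:3) {
    set.seed(seed + 100)
    n <- 200L
    y <- rep(0:1, each = n / 2)
    texts <- vapply(seq_len(n), function(i) {
      toks <- sample(sprintf("filler%02d", 1:20), 10, replace = TRUE)
      if (y[i] == 1) toks[sample(10, 2)] <- "marker"
      paste(paste(toks, collapse = " "), ".")
    }, "")
    tok <- as_token_corpus(texts)
    notes <- prepare_notes(tok)
    tab <- toy_embedding(notes$vocab, d = 16L, seed = seed)
    m <- cnn_model(tab, filter_lengths = 1:2, n_maps = 20, seed = seed)
    fit <- fit_cnn(m, notes, y,
                   config = train_config(epochs = 20L, dropout = 0,
                                         batch_size = 4L,
                                         class_weighting = FALSE,
                                         seed = seed))
    expect_lt(fit$trace$train_loss[20], 0.1)
  }
})

test_that("embedding rows update through the word branch only", {
  fx <- train_fixture(n_notes = 20L)
  m <- cnn_model(fx$tab, filter_lengths = 1:2, n_maps = 4,
                 sentence_filter_lengths = c(1, 2), sentence_n_maps = 3,
                 seed = 2)
  # word stream all padding: any embedding change must come from the word
  # branch reading padding rows; rows seen only by the sentence branch stay
  notes <- fx$notes
  notes$word[] <- 2L
  fit <- fit_cnn(m, notes, fx$y,
                 config = fast_train(epochs = 2L, dropout = 0))
  sent_rows <- setdiff(sort(unique(unlist(notes$sentence))), 2L)
  expect_identical(fit$model$embedding[sent_rows, ],
                   m$embedding[sent_rows, ])
  expect_false(identical(fit$model$embedding[2, ], m$embedding[2, ]))
})

test_that("disabling embedding training freezes the table", {
  fx <- train_fixture(n_notes = 20L)
  m <- cnn_model(fx$tab, filter_lengths = 1:2, n_maps = 4, seed = 2)
  fit <- fit_cnn(m, fx$notes, fx$y,
                 config = fast_train(epochs = 2L, train_embedding = FALSE))
  expect_identical(fit$model$embedding, m$embedding)
  fit2 <- fit_cnn(m, fx$notes, fx$y, config = fast_train(epochs = 2L))
  expect_false(identical(fit2$model$embedding, m$embedding))
})

test_that("validation loss is traced on held-out notes", {
  fx <- train_fixture(n_notes = 40L)
  m <- cnn_model(fx$tab, filter_lengths = 1:2, n_maps = 4, seed = 2)
  tr_idx <- 1:30
  va_idx <- 31:40
  sub <- function(i) {
    s <- fx$notes
    s$word <- s$word[i, , drop = FALSE]
    s$sentence <- s$sentence[i]
    s$sentence_lengths <- s$sentence_lengths[i]
    s
  }
  fit <- fit_cnn(m, sub(tr_idx), fx$y[tr_idx], sub(va_idx), fx$y[va_idx],
                 config = fast_train(epochs = 3L))
  expect_true(all(is.finite(fit$trace$valid_loss)))
})
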