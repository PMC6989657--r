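test_that("convolution matches the hand-computed example and shape contract", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  w <- matrix(c(1, 1), nrow = 1)
  expect_equal(conv_feature_map(x, w, 0), matrix(c(3, 5), nrow = 1))
  # zero weights, zero bias -> all-zero map
  expect_equal(conv_feature_map(x, matrix(0, 1, 2), 0),
               matrix(0, 1, 2))
  set.seed(1)
  x2 <- matrix(rnorm(7 * 3), 7, 3)
  w2 <- matrix(rnorm(4 * 2 * 3), 4)
  expect_identical(dim(conv_feature_map(x2, w2, rnorm(4))), c(4L, 6L))
  expect_error(conv_feature_map(matrix(1, 1, 3), w2, rnorm(4)), "shorter")
})

test_that("convolution equals the brute-force oracle on random inputs", {
  set.seed(42)
  for (rep in 1:100) {
    d <- sample(1:5, 1)
    l <- sample(1:4, 1)
    L <- l + sample(0:6, 1)
    n_maps <- sample(1:6, 1)
    x <- matrix(rnorm(L * d), L, d)
    w <- matrix(rnorm(n_maps * l * d), n_maps)
    b <- rnorm(n_maps)
    expect_equal(conv_feature_map(x, w, b), conv_oracle(x, w, b),
                 tolerance = 1e-12)
  }
})

test_that("max-over-time pooling takes the per-map maximum", {
  expect_equal(max_over_time(matrix(c(0.1, 0.5, 0.3), 1)), 0.5)
  expect_equal(max_over_time(matrix(2, 3, 4)), rep(2, 3))
  expect_error(max_over_time(matrix(numeric(0), 1, 0)), "empty")
  set.seed(3)
  for (rep in 1:100) {
    nr <- sample(1:5, 1)
    m <- matrix(rnorm(nr * sample(1:8, 1)), nrow = nr)
    expect_equal(max_over_time(m), apply(m, 1, function(r) max(r)))
  }
})

test_that("sentence embedding pools true lengths only", {
  e <- array(0, dim = c(2, 3, 2))
  e[1, 1, ] <- c(1, 0)
  e[1, 2, ] <- c(3, 2)
  e[1, 3, ] <- c(99, 99)  # padding position, must not contribute
  expect_equal(sentence_embed(e, c(2, 0), mode = "average"),
               rbind(c(2, 1), c(0, 0)))
  expect_equal(sentence_embed(e, c(2, 0), mode = "sum"),
               rbind(c(4, 2), c(0, 0)))
  # appending padding leaves the pooled row unchanged
  e_wide <- array(0, dim = c(2, 5, 2))
  e_wide[, 1:3, ] <- e
  expect_equal(sentence_embed(e_wide, c(2, 0), mode = "sum"),
               sentence_embed(e, c(2, 0), mode = "sum"))
})

make_models <- function(notes, tab, seed = 2L) {
  w <- cnn_model(tab, filter_lengths = 1:2, n_maps = 4, seed = seed)
  ws <- cnn_model(tab, filter_lengths = 1:2, n_maps = 4,
                  sentence_filter_lengths = c(1, 2), sentence_n_maps = 3,
                  pooling = "sum", seed = seed)
  # share the word-branch parameters exactly
  ws$word_filters <- w$word_filters
  ws$w_out[seq_along(w$w_out)] <- w$w_out
  ws$b_out <- w$b_out
  list(w = w, ws = ws)
}

test_that("forward output is a probability; zero output layer gives 0.5", {
  corpus <- tiny_corpus(n_notes = 8L)
  notes <- prepare_notes(corpus)
  tab <- toy_embedding(notes$vocab)
  m <- cnn_model(tab, filter_lengths = 1:2, n_maps = 4, seed = 1)
  p <- predict(m, notes)
  expect_length(p, 8L)
  expect_true(all(p > 0 & p < 1))
  m$w_out[] <- 0
  m$b_out <- 0
  expect_equal(predict(m, notes), rep(0.5, 8))
})

test_that("ws-CNN with zero sentence branch reproduces the w-CNN", {
  corpus <- tiny_corpus(n_notes = 10L)
  notes <- prepare_notes(corpus)
  tab <- toy_embedding(notes$vocab)
  ms <- make_models(notes, tab)
  ws <- ms$ws
  # zero the sentence filters and their output weights
  for (g in seq_along(ws$sent_filters)) {
    ws$sent_filters[[g]]$W[] <- 0
    ws$sent_filters[[g]]$b[] <- 0
  }
  nw <- length(ms$w$w_out)
  ws$w_out[(nw + 1):length(ws$w_out)] <- 0
  expect_equal(predict(ws, notes), predict(ms$w, notes), tolerance = 1e-12)
})

test_that("forward pass is deterministic without dropout, stochastic with", {
  corpus <- tiny_corpus(n_notes = 6L)
  notes <- prepare_notes(corpus)
  tab <- toy_embedding(notes$vocab)
  m <- cnn_model(tab, filter_lengths = 1:2, n_maps = 4, seed = 1)
  expect_identical(predict(m, notes), predict(m, notes))
  set.seed(1)
  a <- predict(m, notes, dropout = 0.5, dropout_active = TRUE)
  set.seed(1)
  b <- predict(m, notes, dropout = 0.5, dropout_active = TRUE)
  set.seed(2)
  c2 <- predict(m, notes, dropout = 0.5, dropout_active = TRUE)
  expect_identical(a, b)
  expect_false(identical(a, c2))
})

test_that("feature-vector length is conserved across branches", {
  corpus <- tiny_corpus(n_notes = 4L)
  notes <- prepare_notes(corpus)
  tab <- toy_embedding(notes$vocab)
  m <- cnn_model(tab, filter_lengths = c(1, 3, 5), n_maps = 7,
                 sentence_filter_lengths = c(1, 2), sentence_n_maps = 5)
  expect_identical(m$n_features, 3L * 7L + 2L * 5L)
  expect_length(m$w_out, m$n_features)
})

test_that("appending weak padding windows never changes pooled features", {
  # conv responses of appended rows are <= existing maxima by construction
  set.seed(9)
  x <- matrix(abs(rnorm(6 * 2)) + 1, 6, 2)
  w <- matrix(abs(rnorm(3 * 2)), 3)  # positive weights
  b <- rep(0, 3)
  base <- max_over_time(conv_feature_map(x, w, b))
  padded <- rbind(x, matrix(0, 4, 2))  # zero rows respond with 0 <= max
  expect_equal(max_over_time(conv_feature_map(padded, w, b)), base)
})

test_that("phenotype architectures follow the study settings", {
  expect_identical(phenotype_architecture("Adv. Cancer")$filter_lengths, 1:4)
  expect_identical(phenotype_architecture("Adv. Heart Disease")$filter_lengths,
                   1:5)
  expect_identical(phenotype_architecture("Chronic Pain")$filter_lengths, 2:5)
  expect_identical(phenotype_architecture("Chronic Pain")$pooling, "sum")
  expect_identical(phenotype_architecture("Obesity")$pooling, "average")
})

test_that("model checkpoints round-trip through JSON", {
  corpus <- tiny_corpus(n_notes = 5L)
  notes <- prepare_notes(corpus)
  tab <- toy_embedding(notes$vocab)
  m <- cnn_model(tab, filter_lengths = 1:2, n_maps = 3,
                 sentence_filter_lengths = c(1, 2), sentence_n_maps = 2,
                 pooling = "sum", seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_model(m, path)
  m2 <- read_cnn_model(path)
  expect_equal(predict(m2, notes), predict(m, notes), tolerance = 1e-12)
})
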