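test_that("token frequencies count exactly with first-appearance tie-break", {
  tab <- token_frequencies(list(c("a", "a", "b")))
  expect_identical(tab$token, c("a", "b"))
  expect_identical(tab$freq, c(2L, 1L))
  expect_identical(tab$rank, 1:2)
  # ties keep appearance order
  tab2 <- token_frequencies(list(c("z", "y", "z", "y", "x")))
  expect_identical(tab2$token, c("z", "y", "x"))
  # conservation
  corpus <- tiny_corpus(n_notes = 10L)
  docs <- lapply(as_token_corpus(corpus), `[[`, "words")
  tab3 <- token_frequencies(docs)
  expect_identical(sum(tab3$freq), length(unlist(docs)))
})

test_that("singleton tally matches the generator's bookkeeping", {
  corpus <- tiny_corpus(seed = 13L)
  tab <- token_frequencies(as_token_corpus(corpus))
  noise <- tab[startsWith(tab$token, "noise"), ]
  expect_true(all(noise$freq == 1L))
  expect_identical(sort(noise$token), sort(corpus$singleton_tokens))
})

test_that("zipf_fit recovers exact power laws and matches the lm oracle", {
  ranks <- 1:200
  tab <- data.frame(token = paste0("t", ranks),
                    freq = 1e6 * ranks^(-1), rank = ranks)
  fit <- zipf_fit(tab, 10, 150)
  expect_equal(fit$alpha, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  tab$freq <- rep(500, 200)
  expect_equal(zipf_fit(tab, 10, 150)$alpha, 0, tolerance = 1e-12)
  # independent least-squares oracle on noisy windows
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    tab <- data.frame(token = paste0("t", 1:n),
                      freq = exp(rnorm(n, 5, 1)), rank = 1:n)
    lo <- sample(1:5, 1)
    hi <- sample((lo + 5):n, 1)
    fit <- zipf_fit(tab, lo, hi)
    ora <- lm(log10(freq) ~ log10(rank), data = tab[lo:hi, ])
    expect_equal(fit$alpha, -unname(coef(ora)[2]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(coef(ora)[1]), tolerance = 1e-9)
    expect_equal(fit$r_squared, summary(ora)$r.squared, tolerance = 1e-9)
  }
  expect_error(zipf_fit(tab, 10, 10000), "exceeds")
  expect_error(zipf_fit(tab[1:5, ], 1, 2), "rank_lo|3 points")
})

test_that("cumulative fraction is normalized and nondecreasing", {
  tab <- data.frame(token = c("a", "b"), freq = c(3, 1), rank = 1:2)
  expect_equal(cumulative_fraction(tab, 1, 2), c(0.75, 1))
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    tab <- data.frame(token = paste0("t", 1:n),
                      freq = sort(sample(1:500, n, TRUE), decreasing = TRUE),
                      rank = 1:n)
    cf <- cumulative_fraction(tab, 1, n)
    expect_true(all(diff(cf) >= 0))
    expect_equal(cf[n], 1)
  }
})

test_that("frequency filtering drops rare types and conserves the rest", {
  texts <- c("a a a b .", "a c .")
  tok <- as_token_corpus(texts)
  res <- frequency_filter(tok, theta = 1)
  expect_identical(res$n_removed, 2L)  # b and c (the period recurs)
  expect_setequal(res$removed, c("b", "c"))
  expect_identical(res$corpus[[1]]$words, c("a", "a", "a", "."))
  expect_identical(res$corpus[[2]]$words, c("a", "."))
  # theta = 0 removes nothing
  res0 <- frequency_filter(tok, theta = 0)
  expect_identical(res0$n_removed, 0L)
  expect_identical(lapply(res0$corpus, `[[`, "words"),
                   lapply(tok, `[[`, "words"))
  expect_identical(res$n_removed + res$n_remaining, res0$n_remaining)
  expect_error(frequency_filter(tok, -1), "theta")
  # surviving occurrences are conserved on random corpora
  corpus <- as_token_corpus(tiny_corpus(n_notes = 15L))
  for (theta in c(1, 3)) {
    out <- frequency_filter(corpus, theta)
    before <- token_frequencies(corpus)
    after <- token_frequencies(out$corpus)
    keep <- before[before$freq > theta, ]
    expect_identical(sort(after$token), sort(keep$token))
    expect_identical(after$freq[match(keep$token, after$token)], keep$freq)
  }
})

test_that("category filtering keeps selected categories exactly", {
  corpus <- as_token_corpus(tiny_corpus(n_notes = 12L))
  cmap <- tiny_corpus(n_notes = 12L)$category_map
  all_cats <- token_categories()
  full <- filter_by_categories(corpus, cmap, all_cats)
  # identity up to uncategorized punctuation
  freqs <- token_frequencies(full)
  expect_true(all(!freqs$token %in% c(".", ",")))
  expect_true(all(cmap[freqs$token] %in% all_cats))
  expect_warning(empty <- filter_by_categories(corpus, cmap, character(0)),
                 "empty")
  expect_true(all(vapply(empty, function(n) length(n$words), 0L) == 0L))
  # token counts partition across categories
  per_cat <- vapply(all_cats, function(ct)
    sum(token_frequencies(filter_by_categories(corpus, cmap, ct))$freq), 0)
  expect_equal(sum(per_cat), sum(token_frequencies(full)$freq))
  expect_error(filter_by_categories(corpus, cmap, "bogus"), "subset")
})

test_that("greedy removal ranks a pure-noise category first out", {
  # counting evaluator: performance = fraction of notes whose signal-token
  # count agrees with the label (cheap, deterministic)
  corpus <- tiny_corpus(seed = 21L, n_notes = 40L)
  tok <- as_token_corpus(corpus)
  sig <- corpus$truth[["phenotype_01"]]
  y <- corpus$labels[, "phenotype_01"]
  evaluator <- function(filtered) {
    has <- vapply(filtered, function(n) any(n$words %in% sig), TRUE)
    mean(has == (y == 1))
  }
  trace <- greedy_category_removal(tok, corpus$category_map, evaluator)
  expect_s3_class(trace, "greedy_trace")
  expect_setequal(trace$rank, seq_len(nrow(trace)))
  expect_identical(sort(trace$category), sort(token_categories()))
  # the signal category survives to rank 1: removing it drops performance
  expect_identical(trace$category[trace$rank == 1], "symptoms")
  # categories with no effect on the evaluator are removed before symptoms
  expect_true(all(trace$rank[trace$category != "symptoms"] > 1))
})

test_that("two-category greedy removes the uninformative one first", {
  texts <- c("good noise .", "noise noise .", "good good .", "noise good .")
  tok <- as_token_corpus(texts)
  cmap <- c(good = "symptoms", noise = "others")
  y <- c(1, 0, 1, 0)
  evaluator <- function(filtered) {
    score <- vapply(filtered, function(n) sum(n$words == "good"), 0)
    suppressWarnings(compute_metrics(score / 2, y)$auroc)
  }
  trace <- greedy_category_removal(tok, cmap, evaluator,
                                   categories = c("symptoms", "others"))
  expect_identical(trace$category[trace$step == 1], "others")
  expect_identical(trace$category[trace$rank == 1], "symptoms")
})

test_that("information content and required sample size follow the formulas", {
  ic <- information_content(1000, 0.01)
  expect_equal(ic$psi, 10)
  expect_identical(required_sample_size(1000, 0.02, 0.02), 1000L)
  expect_identical(required_sample_size(1000, 0.02, 0.01), 2000L)
  expect_identical(required_sample_size(100, 0.015, 0.01), 150L)
  expect_error(information_content(0, 0.5), "n must")
  expect_error(information_content(10, 0), "p_t")
  expect_error(required_sample_size(10, 0.5, 0), "positive")
})
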