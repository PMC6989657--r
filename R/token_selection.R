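#' The seven token categories
#'
#' Semantic categories used for token prioritization: symptoms,
#' descriptions, medicine, body (body-related), numbers, verbs, others.
#' @return Character vector of the seven category names.
#' @export
token_categories <- function() {
  c("symptoms", "descriptions", "medicine", "body", "numbers", "verbs",
    "others")
}

#' Corpus token frequencies, rank-ordered
#'
#' Exact occurrence counts over the whole corpus; ranks are assigned by
#' descending frequency with ties broken by first appearance.
#'
#' @param corpus A list of token vectors, a `token_corpus`, or a
#'   `synthetic_corpus`.
#' @return A `frequency_table`: data frame with `token`, `freq`, `rank`
#'   (rows ordered by rank).
#' @export
token_frequencies <- function(corpus) {
  docs <- corpus_documents(corpus)
  toks <- unlist(docs, use.names = FALSE)
  uniq <- unique(toks)                    # first-appearance order
  freq <- tabulate(match(toks, uniq), nbins = length(uniq))
  ord <- order(-freq)                     # stable: ties keep appearance order
  df <- data.frame(token = uniq[ord], freq = freq[ord],
                   rank = seq_along(uniq), stringsAsFactors = FALSE)
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Fit a power law to the rank-frequency distribution
#'
#' Ordinary least squares of log10(frequency) on log10(rank) over the
#' closed rank window; the Zipf exponent is minus the slope. Implemented in
#' closed form (so standard regression routines stay available as an
#' independent check).
#'
#' @param table A [token_frequencies()] result.
#' @param rank_lo,rank_hi Closed rank window (defaults 10-1500).
#' @return A `zipf_fit`: list with `alpha`, `intercept`, `r_squared`,
#'   `rank_lo`, `rank_hi`.
#' @export
zipf_fit <- function(table, rank_lo = 10L, rank_hi = 1500L) {
  if (rank_lo >= rank_hi) stop("rank_lo must be below rank_hi")
  if (rank_hi > nrow(table)) stop("rank_hi exceeds the table size")
  win <- table[table$rank >= rank_lo & table$rank <= rank_hi, ]
  if (nrow(win) < 3) stop("fit window has fewer than 3 points")
  x <- log10(win$rank)
  y <- log10(win$freq)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  structure(list(alpha = -slope, intercept = intercept,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 rank_lo = rank_lo, rank_hi = rank_hi),
            class = "zipf_fit")
}

#' @export
print.zipf_fit <- function(x, ...) {
  cat(sprintf("Zipf fit over ranks %d-%d: alpha = %.3f (R^2 = %.3f)\n",
              x$rank_lo, x$rank_hi, x$alpha, x$r_squared))
  invisible(x)
}

#' Relative cumulative sum of token frequencies over a rank window
#'
#' Partial sums of the window frequencies divided by the window total;
#' nondecreasing, ending exactly at 1.
#'
#' @inheritParams zipf_fit
#' @return Numeric vector in [0, 1], one value per rank in the window.
#' @export
cumulative_fraction <- function(table, rank_lo = 10L, rank_hi = 1500L) {
  if (rank_lo > rank_hi) stop("rank_lo must not exceed rank_hi")
  if (rank_hi > nrow(table)) stop("rank_hi exceeds the table size")
  win <- table$freq[table$rank >= rank_lo & table$rank <= rank_hi]
  cumsum(win) / sum(win)
}

filter_note <- function(note, drop) {
  list(words = note$words[!note$words %in% drop],
       sentences = Filter(length, lapply(note$sentences, function(s)
         s[!s %in% drop])))
}

apply_token_filter <- function(corpus, drop) {
  out <- lapply(corpus, filter_note, drop = drop)
  attributes(out) <- attributes(corpus)
  out
}

#' Remove low-frequency token types from a corpus
#'
#' Token types with corpus frequency `<= theta` are deleted from every
#' document (occurrences are dropped, shortening the sequences, not mapped
#' to `unk`). `theta = 0` removes nothing; `theta = 1` removes singleton
#' tokens -- the spelling-error analogues that cannot appear in both a
#' training and a test sample.
#'
#' @param corpus A `token_corpus` (or anything [as_token_corpus()] accepts).
#' @param theta Frequency threshold (>= 0).
#' @return List with `corpus` (the filtered `token_corpus`), `n_removed`
#'   and `n_remaining` token-type counts, and `removed` (the removed types).
#' @export
frequency_filter <- function(corpus, theta) {
  if (theta < 0) stop("theta must be >= 0")
  corpus <- as_token_corpus(corpus)
  tab <- token_frequencies(corpus)
  drop <- tab$token[tab$freq <= theta]
  list(corpus = apply_token_filter(corpus, drop),
       n_removed = length(drop), n_remaining = nrow(tab) - length(drop),
       removed = drop)
}

#' Keep only tokens from selected categories
#'
#' @param corpus A `token_corpus`.
#' @param category_map Named character vector token -> category (a total
#'   function over the corpus's real tokens).
#' @param kept Character vector of categories to keep (subset of
#'   [token_categories()]).
#' @return The filtered `token_corpus` (empty documents possible; an empty
#'   `kept` set empties every document, with a warning).
#' @export
filter_by_categories <- function(corpus, category_map, kept) {
  corpus <- as_token_corpus(corpus)
  if (length(kept) == 0)
    warning("empty category set: all documents will be empty")
  if (!all(kept %in% token_categories()))
    stop("kept must be a subset of token_categories()")
  types <- unique(unlist(lapply(corpus, `[[`, "words"), use.names = FALSE))
  cat_of <- category_map[types]
  drop <- types[is.na(cat_of) | !cat_of %in% kept]
  apply_token_filter(corpus, drop)
}

#' Greedy token-category removal
#'
#' Starting from all categories, repeatedly removes the category whose
#' removal leaves the highest evaluator performance (equivalently, costs
#' the least performance), until one category survives. Ties break by
#' category name order. Rank `K + 1 - step` is assigned to the category
#' removed at `step`; the survivor gets rank 1, so rank 1 marks the most
#' important category (removed last or never).
#'
#' @param corpus A `token_corpus` with labels.
#' @param category_map Named character vector token -> category.
#' @param evaluator Function taking a filtered `token_corpus` and returning
#'   a scalar performance (higher is better); see [cnn_evaluator()].
#' @param categories Categories to consider (default all seven).
#' @return A `greedy_trace`: data frame with `category`, `rank`, `step`
#'   (0 for the survivor) and `performance` after the removal, plus
#'   attribute `performance_all` (before any removal).
#' @export
greedy_category_removal <- function(corpus, category_map, evaluator,
                                    categories = token_categories()) {
  corpus <- as_token_corpus(corpus)
  kept <- sort(categories)
  n_cat <- length(kept)
  perf_all <- evaluator(filter_by_categories(corpus, category_map, kept))
  rows <- list()
  step <- 0L
  while (length(kept) > 1L) {
    step <- step + 1L
    perfs <- vapply(kept, function(cand)
      evaluator(filter_by_categories(corpus, category_map,
                                     setdiff(kept, cand))), 0)
    best <- kept[which.max(perfs)]  # which.max: first = name-order tiebreak
    rows[[step]] <- data.frame(category = best, rank = n_cat + 1L - step,
                               step = step, performance = max(perfs),
                               stringsAsFactors = FALSE)
    kept <- setdiff(kept, best)
  }
  rows[[step + 1L]] <- data.frame(category = kept, rank = 1L, step = 0L,
                                  performance = NA_real_,
                                  stringsAsFactors = FALSE)
  trace <- do.call(rbind, rows)
  trace <- trace[order(trace$rank), ]
  rownames(trace) <- NULL
  attr(trace, "performance_all") <- perf_all
  class(trace) <- c("greedy_trace", "data.frame")
  trace
}

#' CNN-based evaluator for greedy category selection
#'
#' Returns a closure that scores a (filtered) corpus by training the
#' configured CNN on a stratified split and returning the held-out metric.
#' Embeddings are trained once on the unfiltered corpus at creation time
#' and re-aligned to each filtered corpus's vocabulary, mirroring the reuse
#' of pretrained embeddings across selection steps.
#'
#' @param corpus The unfiltered labeled corpus (for embedding pretraining).
#' @param phenotype Label column to classify.
#' @param metric `"f1"` (default) or `"auroc"`.
#' @param model_args Arguments for [cnn_model()].
#' @param train_config A [train_config()].
#' @param embedding_config Used to pretrain the embeddings.
#' @param holdout Fraction of notes held out for scoring.
#' @param seed Seed for the split and training.
#' @return Function: `token_corpus -> scalar performance`.
#' @export
cnn_evaluator <- function(corpus, phenotype, metric = c("f1", "auroc"),
                          model_args = list(),
                          train_config = phenocnn::train_config(),
                          embedding_config = phenocnn::embedding_config(),
                          holdout = 0.3, seed = 1L) {
  metric <- match.arg(metric)
  corpus <- as_token_corpus(corpus)
  labels <- attr(corpus, "labels")
  if (is.null(labels) || !phenotype %in% colnames(labels))
    stop("corpus must carry labels containing the phenotype")
  y <- as.integer(labels[, phenotype])
  raw <- train_cbow(corpus, embedding_config)
  set.seed(as.integer(seed))
  test_idx <- sort(c(
    sample(which(y == 1), max(1L, round(holdout * sum(y == 1)))),
    sample(which(y == 0), max(1L, round(holdout * sum(y == 0))))))
  function(filtered) {
    notes <- prepare_notes(filtered)
    tab <- align_to_vocabulary(raw, notes$vocab, seed = seed)
    train_idx <- setdiff(seq_along(y), test_idx)
    model <- do.call(cnn_model,
                     c(list(embedding = tab), model_args, list(seed = seed)))
    fit <- fit_cnn(model, note_subset(notes, train_idx), y[train_idx],
                   config = train_config)
    scores <- predict(fit$model, note_subset(notes, test_idx))
    m <- suppressWarnings(compute_metrics(scores, y[test_idx]))
    m[[metric]]
  }
}

#' Information content of a data set
#'
#' `psi = N * p_t`: sample size times the fraction of informative tokens.
#' Data sets with higher psi can support more complex models.
#'
#' @param n Sample count N (>= 1).
#' @param p_t Fraction of informative tokens in (0, 1].
#' @return An `info_content`: list with `n`, `p_t`, `psi`.
#' @export
information_content <- function(n, p_t) {
  if (n < 1) stop("n must be >= 1")
  if (p_t <= 0 || p_t > 1) stop("p_t must lie in (0, 1]")
  structure(list(n = n, p_t = p_t, psi = n * p_t), class = "info_content")
}

#' @export
print.info_content <- function(x, ...) {
  cat(sprintf("information content psi = N x p_t = %g x %g = %g\n",
              x$n, x$p_t, x$psi))
  invisible(x)
}

#' Required sample size to match a reference information content
#'
#' Matching `N * p_t = N' * p_t'` gives `N = ceil(N' * p_t' / p_t)`: data
#' with a smaller informative-token fraction need proportionally more
#' samples.
#'
#' @param n_ref Reference sample size N'.
#' @param p_ref Reference informative fraction p_t'.
#' @param p_t Informative fraction of the data at hand (> 0).
#' @return Integer sample size.
#' @export
required_sample_size <- function(n_ref, p_ref, p_t) {
  if (p_t <= 0) stop("p_t must be positive")
  if (p_ref <= 0 || p_ref > 1) stop("p_ref must lie in (0, 1]")
  as.integer(ceiling(n_ref * p_ref / p_t))
}

#' Write a frequency table or greedy trace as CSV
#' @param x A `frequency_table` or `greedy_trace`.
#' @param path Output path.
#' @export
write_selection_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a token category map from TSV (token TAB category)
#' @param path Input path.
#' @return Named character vector token -> category.
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  stats::setNames(df$category, df$token)
}
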