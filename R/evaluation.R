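#' Binary classification metrics
#'
#' Precision, recall and F1 from predictions thresholded at `threshold`;
#' AUROC from the rank statistic (Mann-Whitney with midrank tie
#' correction). Precision is defined as 1 when nothing is predicted
#' positive, recall requires at least one positive label.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold for precision/recall/F1.
#' @return A `metric_set`: list with `precision`, `recall`, `f1`, `auroc`
#'   (AUROC is `NA` with a warning when only one class is present).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(recall) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: labels contain a single class")
    auroc <- NA_real_
  } else {
    r <- rank(scores)  # midranks handle ties
    auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 auroc = auroc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  AUROC %.4f\n",
              x$precision, x$recall, x$f1, x$auroc))
  invisible(x)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop(sprintf("class %s has %d samples, fewer than k = %d folds",
                   cls, length(idx), k))
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

metric_names <- c("precision", "recall", "f1", "auroc")

summarize_folds <- function(per_fold) {
  means <- colMeans(per_fold[metric_names], na.rm = TRUE)
  ses <- vapply(per_fold[metric_names], function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), 0)
  list(mean = means, se = ses)
}

# resolve corpus + labels + embeddings into the shared CV ingredients
cv_ingredients <- function(corpus, phenotype, embeddings, embedding_cfg,
                           case_sensitive, seed) {
  corpus <- as_token_corpus(corpus)
  labels <- attr(corpus, "labels")
  if (is.null(labels)) stop("corpus carries no labels")
  if (!phenotype %in% colnames(labels))
    stop(sprintf("phenotype '%s' not found in the labels", phenotype))
  y <- as.integer(labels[, phenotype])
  notes <- prepare_notes(corpus, case_sensitive = case_sensitive)
  if (is.null(embeddings))
    embeddings <- train_cbow(corpus, embedding_cfg)
  table <- align_to_vocabulary(embeddings, notes$vocab, seed = seed)
  list(notes = notes, y = y, table = table)
}

note_subset <- function(notes, idx) {
  structure(list(word = notes$word[idx, , drop = FALSE],
                 sentence = notes$sentence[idx],
                 sentence_lengths = notes$sentence_lengths[idx],
                 word_lengths = notes$word_lengths[idx],
                 ids = notes$ids[idx], labels = NULL, vocab = notes$vocab,
                 l_max = notes$l_max, w_max = notes$w_max,
                 s_max = notes$s_max),
            class = "note_set")
}

run_cv <- function(ing, model_args, tc, k, seed, fractions,
                   threshold = 0.5) {
  y <- ing$y
  set.seed(as.integer(seed))
  folds <- stratified_folds(y, k)
  fold_seeds <- sample.int(.Machine$integer.max %/% 4L, k)
  out <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    rows <- vector("list", k)
    for (fold in seq_len(k)) {
      test_idx <- which(folds == fold)
      train_idx <- which(folds != fold)
      if (frac < 1) {
        set.seed(fold_seeds[fold] + fi)
        keep <- sample(length(train_idx),
                       max(1L, round(frac * length(train_idx))))
        train_idx <- train_idx[keep]
      }
      ytr <- y[train_idx]
      if (length(unique(ytr)) < 2L) {
        warning(sprintf(
          "fold %d at fraction %.2f has a single training class; skipped",
          fold, frac))
        rows[[fold]] <- data.frame(fold = fold, precision = NA, recall = NA,
                                   f1 = NA, auroc = NA)
        next
      }
      args <- c(list(embedding = ing$table), model_args,
                list(seed = fold_seeds[fold]))
      model <- do.call(cnn_model, args)
      tc_fold <- tc
      tc_fold$seed <- fold_seeds[fold]
      fit <- fit_cnn(model, note_subset(ing$notes, train_idx), ytr,
                     config = tc_fold)
      scores <- predict(fit$model, note_subset(ing$notes, test_idx))
      m <- suppressWarnings(compute_metrics(scores, y[test_idx], threshold))
      rows[[fold]] <- data.frame(fold = fold, precision = m$precision,
                                 recall = m$recall, f1 = m$f1,
                                 auroc = m$auroc)
    }
    per_fold <- do.call(rbind, rows)
    s <- summarize_folds(per_fold)
    out[[fi]] <- structure(list(per_fold = per_fold, mean = s$mean,
                                se = s$se, k = k),
                           class = "cv_summary")
  }
  out
}

#' Stratified k-fold cross-validation of a phenotype classifier
#'
#' One-vs-rest evaluation: the named phenotype is the positive class and
#' all remaining notes the negative class. The vocabulary and embedding
#' table are built once on the full corpus (embedding training is
#' unsupervised); the classifier is trained from scratch in each fold and
#' scored on the held-out notes. Folds are stratified on the target label
#' so minority-class folds stay populated.
#'
#' @param corpus A labeled corpus (`synthetic_corpus` or `token_corpus`
#'   with a `labels` attribute).
#' @param phenotype Column name in the labels.
#' @param embeddings Optional pretrained raw embedding map (matrix with
#'   token rownames); trained with CBOW on the corpus when `NULL`.
#' @param model_args List of arguments for [cnn_model()] other than
#'   `embedding` and `seed` (e.g. `filter_lengths`,
#'   `sentence_filter_lengths`, `pooling`).
#' @param train_config A [train_config()].
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and all per-fold seeds.
#' @param embedding_config Used when `embeddings` is `NULL`.
#' @param case_sensitive Vocabulary case handling.
#' @param threshold Decision threshold for precision/recall/F1.
#' @return A `cv_summary`: per-fold metrics plus mean and standard error
#'   (`SE = sd / sqrt(k)`) per metric.
#' @export
cross_validate <- function(corpus, phenotype, embeddings = NULL,
                           model_args = list(),
                           train_config = phenocnn::train_config(),
                           k = 10L, seed = 1L,
                           embedding_config = phenocnn::embedding_config(),
                           case_sensitive = FALSE, threshold = 0.5) {
  ing <- cv_ingredients(corpus, phenotype, embeddings, embedding_config,
                        case_sensitive, seed)
  check_fold_feasibility(ing$y, k)
  run_cv(ing, model_args, train_config, k, seed, fractions = 1)[[1]]
}

check_fold_feasibility <- function(y, k) {
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop(sprintf(
      "need at least k = %d positives and negatives for stratified folds", k))
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  for (m in metric_names)
    cat(sprintf("  %-9s %6.2f%% +- %.2f%%\n", m, 100 * x$mean[[m]],
                100 * x$se[[m]]))
  invisible(x)
}

#' Learning curve over training-set fractions
#'
#' Re-runs cross-validation while keeping the test folds fixed and
#' uniformly subsampling each fold's training split to the given fraction,
#' so performance differences reflect training-set size only. Fraction 1.0
#' reproduces [cross_validate()] exactly under the same seed.
#'
#' @inheritParams cross_validate
#' @param fractions Sorted vector of training fractions in (0, 1].
#' @return A `learning_curve`: list with `fractions` and a `cv_summary`
#'   per fraction.
#' @export
learning_curve <- function(corpus, phenotype, fractions = c(0.1, 0.5, 1),
                           embeddings = NULL, model_args = list(),
                           train_config = phenocnn::train_config(),
                           k = 10L, seed = 1L,
                           embedding_config = phenocnn::embedding_config(),
                           case_sensitive = FALSE, threshold = 0.5) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be sorted increasingly")
  ing <- cv_ingredients(corpus, phenotype, embeddings, embedding_config,
                        case_sensitive, seed)
  check_fold_feasibility(ing$y, k)
  summaries <- run_cv(ing, model_args, train_config, k, seed, fractions)
  structure(list(fractions = fractions, summaries = summaries, k = k),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve (%d-fold CV per fraction)\n", x$k))
  for (i in seq_along(x$fractions))
    cat(sprintf("  fraction %.2f: AUROC %6.2f%% +- %.2f%%, F1 %6.2f%% +- %.2f%%\n",
                x$fractions[i], 100 * x$summaries[[i]]$mean[["auroc"]],
                100 * x$summaries[[i]]$se[["auroc"]],
                100 * x$summaries[[i]]$mean[["f1"]],
                100 * x$summaries[[i]]$se[["f1"]]))
  invisible(x)
}

#' Write per-fold CV metrics as CSV and the mean/SE summary as JSON
#'
#' @param cv A `cv_summary`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @param phenotype Phenotype name recorded in the CSV.
#' @export
write_cv_metrics <- function(cv, csv_path = NULL, json_path = NULL,
                             phenotype = NA_character_) {
  if (!is.null(csv_path)) {
    df <- cbind(phenotype = phenotype, cv$per_fold)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(mean = as.list(cv$mean), se = as.list(cv$se),
                              k = cv$k),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
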