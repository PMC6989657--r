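#' Training configuration
#'
#' Defaults follow the study protocol: Adadelta with learning rate 0.5,
#' mini-batches of 32, 20 epochs, dropout 0.5 on the penultimate feature
#' vector, filter weights projected to a max norm of 3 after every update,
#' and uniform(-0.01, 0.01) initialization.
#'
#' @param learning_rate Adadelta learning-rate multiplier.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (0 leaves the initialized model untouched).
#' @param dropout Dropout rate on the penultimate feature vector.
#' @param max_norm Maximum L2 norm per filter weight vector (0 disables).
#' @param init_range Half-width of the uniform weight initialization.
#' @param class_weighting Weight each class's loss by 1/#samples?
#' @param train_embedding Fine-tune the embedding table (via word-branch
#'   gradients only)?
#' @param rho,epsilon Adadelta decay and numerical constant (published
#'   defaults).
#' @param seed Integer seed for shuffling, dropout masks and initialization.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.5, batch_size = 32L, epochs = 20L,
                         dropout = 0.5, max_norm = 3, init_range = 0.01,
                         class_weighting = TRUE, train_embedding = TRUE,
                         rho = 0.95, epsilon = 1e-6, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 0) stop("epochs must be >= 0")
  if (max_norm < 0) stop("max_norm must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 max_norm = max_norm, init_range = init_range,
                 class_weighting = isTRUE(class_weighting),
                 train_embedding = isTRUE(train_embedding),
                 rho = rho, epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `weight_c = 1 / n_c`: the loss contribution of each class is scaled by
#' the reciprocal of its sample count, so false predictions on the minority
#' class are penalized more strongly.
#'
#' @param label_counts Named or unnamed vector of per-class counts (all >= 1).
#' @return Numeric vector of weights, same names as the input.
#' @export
compute_class_weights <- function(label_counts) {
  if (any(label_counts < 1)) stop("all class counts must be >= 1")
  1 / label_counts
}

#' Class-weighted binary cross-entropy
#'
#' `loss = -w_y * (y log p + (1 - y) log(1 - p))`, with p clamped to
#' `[eps, 1 - eps]` so boundary probabilities stay finite.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (0/1), recycled against `p`.
#' @param weights Length-2 vector `c(negative, positive)` of class weights.
#' @param eps Clamping epsilon.
#' @return Nonnegative losses, one per element of `p`.
#' @export
weighted_cross_entropy <- function(p, y, weights = c(1, 1), eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- ifelse(y == 1, weights[2], weights[1])
  -w * (y * log(p) + (1 - y) * log(1 - p))
}

subset_note_set <- function(x, idx) {
  list(word = x$word[idx, , drop = FALSE],
       sent = x$sentence[idx],
       slen = x$sentence_lengths[idx])
}

#' Train a CNN classifier
#'
#' Cost-sensitive mini-batch training: class-weighted cross-entropy (weights
#' 1/#samples per class when `class_weighting`), Adadelta updates, dropout
#' on the penultimate feature vector, and max-norm projection of every
#' filter weight vector after each step. In the combined model the sentence
#' branch reads the shared embedding table through a detached view, so only
#' word-branch gradients fine-tune the embeddings. Aborts on non-finite
#' loss.
#'
#' @param model A [cnn_model()].
#' @param x A `note_set` with the training notes.
#' @param y Binary labels (0/1) for the rows of `x`.
#' @param valid_x,valid_y Optional held-out set for the per-epoch validation
#'   loss trace.
#' @param config A [train_config()].
#' @return A `cnn_fit`: list with the trained `model` and `trace`, a data
#'   frame of per-epoch train/validation loss.
#' @export
fit_cnn <- function(model, x, y, valid_x = NULL, valid_y = NULL,
                    config = train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  y <- as.integer(y)
  if (length(y) != nrow(x$word)) stop("labels do not match the note set")
  if (length(y) == 0) stop("empty training set")
  counts <- c(sum(y == 0), sum(y == 1))
  cw <- if (config$class_weighting) {
    if (any(counts == 0)) stop("class weighting needs both classes present")
    compute_class_weights(counts)
  } else c(1, 1)
  needs_sent <- model_needs_sentences(model)
  tr <- list(word = x$word,
             sent = if (needs_sent) x$sentence else list(),
             slen = if (needs_sent) x$sentence_lengths else list())
  if (is.null(valid_x)) {
    va <- list(word = matrix(2L, 0, ncol(x$word)), sent = list(),
               slen = list())
    v_y <- integer(0)
  } else {
    va <- list(word = valid_x$word,
               sent = if (needs_sent) valid_x$sentence else list(),
               slen = if (needs_sent) valid_x$sentence_lengths else list())
    v_y <- as.integer(valid_y)
  }
  if (config$epochs == 0L)
    return(structure(list(model = model,
                          trace = data.frame(epoch = integer(0),
                                             train_loss = numeric(0),
                                             valid_loss = numeric(0)),
                          class_weights = cw),
                     class = "cnn_fit"))
  set.seed(config$seed)
  res <- cpp_train_cnn(model$embedding, model$word_filters,
                       model$sent_filters %||% list(),
                       if (model$pooling == "sum") 0L else 1L,
                       model$w_out, model$b_out,
                       tr$word, tr$sent, tr$slen, y, cw,
                       va$word, va$sent, va$slen, v_y,
                       config$learning_rate, config$batch_size,
                       config$epochs, config$dropout, config$max_norm,
                       config$train_embedding && model$trainable_embedding,
                       config$rho, config$epsilon)
  model$embedding <- res$E
  model$word_filters <- res$word_filters
  if (needs_sent) model$sent_filters <- res$sent_filters
  model$w_out <- as.numeric(res$w_out)
  model$b_out <- res$b_out
  trace <- data.frame(epoch = seq_len(config$epochs),
                      train_loss = res$train_loss,
                      valid_loss = res$valid_loss)
  structure(list(model = model, trace = trace, class_weights = cw),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat("Trained CNN classifier\n")
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  %d epochs, final train loss %.4f", last$epoch,
                last$train_loss))
    if (is.finite(last$valid_loss))
      cat(sprintf(", valid loss %.4f", last$valid_loss))
    cat("\n")
  }
  invisible(x)
}

#' Write a loss trace as CSV (epoch, train_loss, valid_loss)
#' @param fit A `cnn_fit`.
#' @param path Output path.
#' @export
write_loss_trace <- function(fit, path) {
  utils::write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}
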