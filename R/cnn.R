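#' Convolutional feature maps over an embedded note
#'
#' Applies one filter group (all filters share length l) along the temporal
#' axis with stride 1 and no padding, followed by a ReLU:
#' `c_i = max(0, w . x_{i:i+l-1} + b)`.
#'
#' @param x L x d numeric matrix (one embedded token per row).
#' @param weights n_maps x (l*d) filter matrix; each row is a flattened
#'   filter (time-major: the first d entries weight the first token).
#' @param bias Length n_maps bias vector.
#' @return n_maps x (L - l + 1) matrix of feature maps.
#' @export
conv_feature_map <- function(x, weights, bias) {
  stopifnot(is.matrix(x), is.matrix(weights))
  l <- ncol(weights) / ncol(x)
  if (l != round(l)) stop("filter width is not a multiple of the embedding dimension")
  if (nrow(x) < l) stop("input shorter than the filter length")
  cpp_conv_feature_map(x, weights, as.numeric(bias))
}

#' Max-over-time pooling
#'
#' Reduces each feature map (row) to its maximum along the temporal axis.
#'
#' @param c_maps n_maps x T matrix of feature maps (T >= 1).
#' @return Numeric vector of length n_maps.
#' @export
max_over_time <- function(c_maps) {
  stopifnot(is.matrix(c_maps))
  if (ncol(c_maps) == 0) stop("empty feature map")
  apply(c_maps, 1, max)
}

#' Pool word embeddings into sentence embeddings
#'
#' Each sentence's embedding is the sum (or average) of its word vectors
#' over the sentence's true length; padding positions never contribute, and
#' an all-padding sentence pools to the zero vector.
#'
#' @param e_prime S x W x d array of embedded tokens.
#' @param lengths Per-sentence true lengths (each <= W).
#' @param mode `"sum"` or `"average"`.
#' @return S x d matrix of sentence embeddings.
#' @export
sentence_embed <- function(e_prime, lengths, mode = c("average", "sum")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(e_prime)) == 3, length(lengths) == dim(e_prime)[1])
  if (any(lengths > dim(e_prime)[2])) stop("length exceeds sentence width")
  d <- dim(e_prime)[3]
  out <- matrix(0, nrow = dim(e_prime)[1], ncol = d)
  for (s in seq_along(lengths)) {
    len <- lengths[s]
    if (len == 0) next
    block <- matrix(e_prime[s, seq_len(len), ], nrow = len, ncol = d)
    out[s, ] <- if (mode == "sum") colSums(block) else colMeans(block)
  }
  out
}

new_filter_group <- function(l, n_maps, d, init_range) {
  list(l = as.integer(l),
       W = matrix(stats::runif(n_maps * l * d, -init_range, init_range),
                  nrow = n_maps),
       b = stats::runif(n_maps, -init_range, init_range))
}

#' Construct a w-CNN or ws-CNN classifier
#'
#' The word branch embeds the token-index sequence, applies one
#' convolutional filter group per filter length with ReLU, and max-over-time
#' pools each feature map. If sentence filter lengths are given, a sentence
#' branch first pools word vectors into per-sentence embeddings (excluding
#' padding) and runs its own filter groups over the sentence sequence; both
#' branches' pooled features are concatenated at the penultimate layer. A
#' single sigmoid unit maps the (dropout-regularized) feature vector V to
#' the positive-class probability `y = sigmoid(w . V + b)`.
#'
#' All weights are initialized uniformly in `[-init_range, init_range]`
#' from `seed`; the embedding table is taken as given (and trained further
#' by [fit_cnn()] through word-branch gradients only).
#'
#' @param embedding An `embedding_table` (vocabulary-aligned matrix).
#' @param filter_lengths Word-branch filter lengths (e.g. `1:4`).
#' @param n_maps Feature maps per word-branch filter group.
#' @param sentence_filter_lengths Sentence-branch filter lengths (default
#'   `NULL` builds a word-only model; the combined model uses `c(1,5,7,9)`).
#' @param sentence_n_maps Feature maps per sentence-branch group.
#' @param pooling Sentence-embedding pooling mode, `"average"` or `"sum"`.
#' @param init_range Half-width of the uniform initialization.
#' @param seed Integer seed for the initialization.
#' @return A `cnn_model` object.
#' @export
cnn_model <- function(embedding, filter_lengths = 1:4, n_maps = 100L,
                      sentence_filter_lengths = NULL, sentence_n_maps = 50L,
                      pooling = c("average", "sum"), init_range = 0.01,
                      seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(is.matrix(embedding), length(filter_lengths) >= 1)
  d <- ncol(embedding)
  set.seed(as.integer(seed))
  word_filters <- lapply(filter_lengths, new_filter_group, n_maps = n_maps,
                         d = d, init_range = init_range)
  sent_filters <- if (!is.null(sentence_filter_lengths))
    lapply(sentence_filter_lengths, new_filter_group,
           n_maps = sentence_n_maps, d = d, init_range = init_range)
  n_feat <- as.integer(length(filter_lengths) * n_maps +
    length(sentence_filter_lengths) * sentence_n_maps)
  structure(list(
    embedding = unclass(embedding), word_filters = word_filters,
    sent_filters = sent_filters, pooling = pooling,
    w_out = stats::runif(n_feat, -init_range, init_range),
    b_out = stats::runif(1, -init_range, init_range),
    d = d, n_features = n_feat, trainable_embedding = TRUE),
    class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  kind <- if (is.null(x$sent_filters)) "w-CNN" else "ws-CNN"
  wl <- vapply(x$word_filters, `[[`, 0L, "l")
  cat(sprintf("%s: word filters {%s} x %d maps", kind,
              paste(wl, collapse = ","), nrow(x$word_filters[[1]]$W)))
  if (!is.null(x$sent_filters)) {
    sl <- vapply(x$sent_filters, `[[`, 0L, "l")
    cat(sprintf(", sentence filters {%s} x %d maps (%s pooling)",
                paste(sl, collapse = ","), nrow(x$sent_filters[[1]]$W),
                x$pooling))
  }
  cat(sprintf("\n  d = %d, |V| = %d features, vocab rows = %d\n",
              x$d, x$n_features, nrow(x$embedding)))
  invisible(x)
}

model_needs_sentences <- function(model) !is.null(model$sent_filters)

as_forward_inputs <- function(model, newdata) {
  if (inherits(newdata, "note_set")) {
    list(word = newdata$word,
         sent = if (model_needs_sentences(model)) newdata$sentence else list(),
         slen = if (model_needs_sentences(model)) newdata$sentence_lengths
                else list())
  } else if (is.matrix(newdata)) {
    if (model_needs_sentences(model))
      stop("a ws-CNN needs a note_set with sentence-level input")
    list(word = newdata, sent = list(), slen = list())
  } else stop("newdata must be a note_set or a word-index matrix")
}

#' Forward pass: positive-class probabilities
#'
#' Deterministic with `dropout_active = FALSE` (the default); with dropout
#' active, inverted-dropout masks are applied to the penultimate feature
#' vector, as during training.
#'
#' @param object A `cnn_model`.
#' @param newdata A `note_set` (or an n x L word-index matrix for a w-CNN).
#' @param dropout Dropout rate used when `dropout_active`.
#' @param dropout_active Sample dropout masks?
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.cnn_model <- function(object, newdata, dropout = 0.5,
                              dropout_active = FALSE, ...) {
  inp <- as_forward_inputs(object, newdata)
  cpp_forward_cnn(object$embedding, object$word_filters,
                  object$sent_filters %||% list(),
                  if (object$pooling == "sum") 0L else 1L,
                  object$w_out, object$b_out,
                  inp$word, inp$sent, inp$slen, dropout, dropout_active)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-phenotype architecture settings
#'
#' Filter lengths and sentence-pooling modes tuned per disorder in the
#' phenotyping study: word filter lengths 1-4 for Adv. Cancer, Chronic
#' Neuro, Depression; 2-5 for Adv. Lung Disease, Chronic Pain, Alcohol
#' Abuse, Obesity, Psychiatric Disorders (and, as the package's default for
#' the disorder the published list omits, Substance Abuse); 1-5 for
#' Adv. Heart Disease. Sum pooling for Adv. Cancer, Adv. Heart Disease and
#' Chronic Pain; average pooling otherwise. Unknown phenotype names fall
#' back to filter lengths 1-4 with average pooling.
#'
#' @param phenotype Phenotype name.
#' @return List with `filter_lengths` and `pooling`.
#' @export
phenotype_architecture <- function(phenotype) {
  lengths <- list(
    "Adv. Cancer" = 1:4, "Chronic Neuro" = 1:4, "Depression" = 1:4,
    "Adv. Lung Disease" = 2:5, "Chronic Pain" = 2:5, "Alcohol Abuse" = 2:5,
    "Obesity" = 2:5, "Psychiatric Disorders" = 2:5, "Substance Abuse" = 2:5,
    "Adv. Heart Disease" = 1:5)
  sum_pool <- c("Adv. Cancer", "Adv. Heart Disease", "Chronic Pain")
  list(filter_lengths = lengths[[phenotype]] %||% 1:4,
       pooling = if (phenotype %in% sum_pool) "sum" else "average")
}

#' Model checkpoint I/O (JSON)
#'
#' The full parameter set (embedding table, filter groups, output layer) and
#' architecture config in a single JSON file.
#' @param model A `cnn_model`.
#' @param path File path.
#' @export
write_cnn_model <- function(model, path) {
  jsonlite::write_json(
    list(embedding = model$embedding,
         word_filters = model$word_filters,
         sent_filters = model$sent_filters,
         pooling = model$pooling, w_out = model$w_out, b_out = model$b_out,
         d = model$d, n_features = model$n_features,
         trainable_embedding = model$trainable_embedding),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cnn_model
#' @export
read_cnn_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_group <- function(g)
    list(l = as.integer(g$l), W = as.matrix(g$W), b = as.numeric(g$b))
  restore_groups <- function(gs) {
    if (is.null(gs) || length(gs) == 0) return(NULL)
    if (is.data.frame(gs)) {
      lapply(seq_len(nrow(gs)), function(i)
        list(l = as.integer(gs$l[i]), W = as.matrix(gs$W[[i]]),
             b = as.numeric(gs$b[[i]])))
    } else lapply(gs, as_group)
  }
  structure(list(
    embedding = as.matrix(x$embedding),
    word_filters = restore_groups(x$word_filters),
    sent_filters = restore_groups(x$sent_filters),
    pooling = x$pooling, w_out = as.numeric(x$w_out),
    b_out = as.numeric(x$b_out), d = as.integer(x$d),
    n_features = as.integer(x$n_features),
    trainable_embedding = isTRUE(x$trainable_embedding)),
    class = "cnn_model")
}
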