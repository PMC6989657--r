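#' CBOW embedding training configuration
#'
#' Defaults follow the phenotyping study setup: 50-dimensional vectors, a
#' lookup window of 10, tokens appearing fewer than 5 times filtered out, 10
#' negative samples per positive example, 15 iterations.
#'
#' @param dimension Embedding dimension d.
#' @param window Context window size (tokens each side, randomly shrunk per
#'   position as usual for CBOW).
#' @param min_count Minimum corpus frequency; rarer tokens get no vector.
#' @param negative Negative samples per positive example.
#' @param iterations Passes over the corpus.
#' @param alpha Initial SGD learning rate (linearly decayed).
#' @param seed Integer seed.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(dimension = 50L, window = 10L, min_count = 5L,
                             negative = 10L, iterations = 15L, alpha = 0.05,
                             seed = 1L) {
  cfg <- list(dimension = as.integer(dimension), window = as.integer(window),
              min_count = as.integer(min_count),
              negative = as.integer(negative),
              iterations = as.integer(iterations), alpha = alpha,
              seed = as.integer(seed))
  counts <- c(cfg$dimension, cfg$window, cfg$min_count, cfg$negative,
              cfg$iterations)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  structure(cfg, class = "embedding_config")
}

#' Train CBOW word embeddings
#'
#' Learns distributional vectors by predicting each token from the average
#' of its context window, with negative sampling from the unigram
#' distribution raised to 3/4. Tokens below `min_count` are absent from the
#' result. Reproducible given `config$seed` (single-threaded).
#'
#' @param corpus A list of token vectors (documents), a `token_corpus`, or a
#'   `synthetic_corpus`.
#' @param config An [embedding_config()].
#' @return A numeric matrix, one row per retained token (rownames are the
#'   tokens), `config$dimension` columns.
#' @export
train_cbow <- function(corpus, config = embedding_config()) {
  docs <- corpus_documents(corpus)
  toks <- unlist(docs, use.names = FALSE)
  if (length(toks) == 0) stop("corpus is empty")
  tab <- token_frequencies(docs)
  keep <- tab$token[tab$freq >= config$min_count]
  if (length(keep) == 0)
    stop("no token reaches min_count; lower the threshold")
  id <- stats::setNames(seq_along(keep) - 1L, keep)  # 0-based for C++
  docs_idx <- lapply(docs, function(d) {
    m <- id[d]
    as.integer(m[!is.na(m)])
  })
  docs_idx <- docs_idx[vapply(docs_idx, length, 0L) > 0L]
  counts <- tab$freq[match(keep, tab$token)]
  set.seed(config$seed)
  emb <- cpp_train_cbow(docs_idx, length(keep), as.numeric(counts),
                        config$dimension, config$window, config$negative,
                        config$iterations, config$alpha)
  rownames(emb) <- keep
  emb
}

# documents as flat token vectors, whatever the input representation
corpus_documents <- function(corpus) {
  if (inherits(corpus, "synthetic_corpus"))
    corpus <- as_token_corpus(corpus)
  if (inherits(corpus, "token_corpus"))
    return(lapply(corpus, `[[`, "words"))
  if (is.list(corpus) && length(corpus) > 0 && is.list(corpus[[1]]) &&
      !is.character(corpus[[1]]))
    return(lapply(corpus, function(x) unlist(x, use.names = FALSE)))
  corpus
}

#' Align a raw embedding map to a vocabulary
#'
#' Produces the index-aligned lookup table the networks consume: row i is
#' the vector for vocabulary index i. Tokens present in the raw map copy
#' their vector; absent tokens share the `unk` row, which is initialized
#' uniformly in [-0.01, 0.01]; the `padding` row is all zeros (and excluded
#' from sentence pooling downstream).
#'
#' @param raw A matrix with token rownames, as returned by [train_cbow()]
#'   or [read_word2vec()].
#' @param vocab A [build_vocabulary()] result.
#' @param seed Seed for the `unk` row initialization.
#' @return An `embedding_table`: numeric matrix `length(vocab)` x d.
#' @export
align_to_vocabulary <- function(raw, vocab, seed = 1L) {
  stopifnot(is.matrix(raw), inherits(vocab, "vocabulary"))
  d <- ncol(raw)
  set.seed(as.integer(seed))
  unk_row <- stats::runif(d, -0.01, 0.01)
  tab <- matrix(0, nrow = length(vocab$tokens), ncol = d)
  tab[1, ] <- unk_row
  hit <- match(vocab$tokens, rownames(raw))
  hit[1:2] <- NA  # reserved rows keep their initialization
  found <- which(!is.na(hit))
  if (length(found) > 0) tab[found, ] <- raw[hit[found], , drop = FALSE]
  missing <- setdiff(which(is.na(hit)), 1:2)
  if (length(missing) > 0)
    tab[missing, ] <- matrix(unk_row, nrow = length(missing), ncol = d,
                             byrow = TRUE)
  structure(tab, class = c("embedding_table", "matrix", "array"))
}

#' Word2vec text-format I/O
#'
#' Header line `count dim`, then one `token v1 ... vd` line per token.
#'
#' @param emb Matrix with token rownames.
#' @param path File path.
#' @export
write_word2vec <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1, function(r)
                     paste(sprintf("%.8g", r), collapse = " "))), con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, "", 1L)
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]),
                  numeric(hdr[2])))
  rownames(emb) <- tokens
  if (nrow(emb) != hdr[1]) warning("header count does not match rows read")
  emb
}
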