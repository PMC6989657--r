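#' Configuration for the synthetic clinical-note generator
#'
#' Defines a corpus-generating process with the statistical structure of
#' de-identified discharge summaries: a Zipf-distributed background
#' vocabulary, documents segmented into sentences, once-only noise tokens
#' (the analogue of spelling errors and stray number sequences), and
#' category-tagged signal tokens that are over-represented in notes positive
#' for the corresponding phenotype.
#'
#' @param n_notes Number of notes to generate (>= 2, so the corpus can be
#'   split for cross-validation).
#' @param n_phenotypes Number of binary phenotype labels.
#' @param vocab_size Size of the background vocabulary (>= 10).
#' @param zipf_alpha Exponent of the background rank-frequency power law;
#'   token of rank r is drawn with probability proportional to r^-zipf_alpha.
#' @param signal_tokens_per_phenotype Number of dedicated signal tokens per
#'   phenotype, disjoint from the background vocabulary.
#' @param signal_category Category label assigned to every signal token
#'   (default "symptoms"), so category-prioritization experiments have a
#'   known ground truth.
#' @param signal_rate Probability that a note positive for a phenotype emits
#'   each of that phenotype's signal tokens in a given sentence.
#' @param sentences_per_note Integer range (length 2) of sentences per note.
#' @param words_per_sentence Integer range (length 2) of words per sentence.
#' @param label_prevalences Probability of a positive label, recycled across
#'   phenotypes.
#' @param singleton_rate Probability that an emitted background position is
#'   replaced by a fresh never-reused noise token.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return A `generator_config` object (a validated list).
#' @export
generator_config <- function(n_notes = 500L,
                             n_phenotypes = 10L,
                             vocab_size = 2000L,
                             zipf_alpha = 0.97,
                             signal_tokens_per_phenotype = 10L,
                             signal_category = "symptoms",
                             signal_rate = 0.2,
                             sentences_per_note = c(4L, 10L),
                             words_per_sentence = c(5L, 12L),
                             label_prevalences = 0.25,
                             singleton_rate = 0.01,
                             seed = 1L) {
  cfg <- list(
    n_notes = as.integer(n_notes), n_phenotypes = as.integer(n_phenotypes),
    vocab_size = as.integer(vocab_size), zipf_alpha = zipf_alpha,
    signal_tokens_per_phenotype = as.integer(signal_tokens_per_phenotype),
    signal_category = signal_category, signal_rate = signal_rate,
    sentences_per_note = as.integer(sentences_per_note),
    words_per_sentence = as.integer(words_per_sentence),
    label_prevalences = rep_len(label_prevalences, n_phenotypes),
    singleton_rate = singleton_rate, seed = as.integer(seed))
  if (cfg$n_notes < 2L) stop("n_notes must be at least 2 (cannot split for CV)")
  if (cfg$vocab_size < 10L) stop("vocab_size must be at least 10")
  if (cfg$zipf_alpha <= 0) stop("zipf_alpha must be positive")
  if (cfg$n_phenotypes < 1L || cfg$signal_tokens_per_phenotype < 1L)
    stop("counts must be >= 1")
  probs <- c(cfg$label_prevalences, cfg$signal_rate, cfg$singleton_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$sentences_per_note) != 2L ||
      length(cfg$words_per_sentence) != 2L)
    stop("sentence and word ranges must have length 2")
  if (any(cfg$sentences_per_note < 1L) || any(cfg$words_per_sentence < 1L))
    stop("sentence and word ranges must be >= 1")
  if (!cfg$signal_category %in% token_categories())
    stop("signal_category must be one of the seven token categories")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic note generator config\n")
  cat(sprintf("  notes: %d, phenotypes: %d, background vocab: %d (alpha = %g)\n",
              x$n_notes, x$n_phenotypes, x$vocab_size, x$zipf_alpha))
  cat(sprintf("  signal: %d tokens/phenotype ('%s'), rate %g/sentence\n",
              x$signal_tokens_per_phenotype, x$signal_category, x$signal_rate))
  cat(sprintf("  note shape: %d-%d sentences x %d-%d words, singleton rate %g\n",
              x$sentences_per_note[1], x$sentences_per_note[2],
              x$words_per_sentence[1], x$words_per_sentence[2],
              x$singleton_rate))
  invisible(x)
}

# inverse-CDF sampler over a fixed rank table: exact exponent control,
# rejection-free
sample_zipf <- function(n, vocab_size, alpha) {
  p <- (seq_len(vocab_size))^(-alpha)
  cdf <- cumsum(p) / sum(p)
  findInterval(stats::runif(n), cdf) + 1L
}

#' Generate a synthetic annotated note corpus
#'
#' Draws background tokens by inverse-CDF sampling from a rank table with
#' the configured power-law exponent, assigns each phenotype label
#' independently at its prevalence, injects the phenotype's signal tokens
#' into positive notes at `signal_rate` per sentence, and replaces a
#' `singleton_rate` fraction of background positions with fresh noise tokens
#' that occur exactly once corpus-wide. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_corpus`: list with `notes` (each a list with `id`,
#'   `sentences` as token vectors, and `text`), `labels` (binary matrix
#'   n_notes x n_phenotypes), `category_map` (named character vector over all
#'   generated token types), `truth` (signal tokens per phenotype),
#'   `singleton_tokens` (the emitted noise tokens), and the config.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cfg <- config
  background <- sprintf("tok%04d", seq_len(cfg$vocab_size))
  phenos <- sprintf("phenotype_%02d", seq_len(cfg$n_phenotypes))
  signal <- lapply(seq_len(cfg$n_phenotypes), function(p)
    sprintf("sigp%02dt%02d", p, seq_len(cfg$signal_tokens_per_phenotype)))
  names(signal) <- phenos

  labels <- sapply(seq_len(cfg$n_phenotypes), function(p)
    stats::rbinom(cfg$n_notes, 1L, cfg$label_prevalences[p]))
  labels <- matrix(as.integer(labels), nrow = cfg$n_notes,
                   dimnames = list(sprintf("note_%04d", seq_len(cfg$n_notes)),
                                   phenos))

  singleton_counter <- 0L
  singletons <- character(0)
  notes <- vector("list", cfg$n_notes)
  for (i in seq_len(cfg$n_notes)) {
    n_sent <- sample(cfg$sentences_per_note[1]:cfg$sentences_per_note[2], 1L)
    lens <- sample(cfg$words_per_sentence[1]:cfg$words_per_sentence[2],
                   n_sent, replace = TRUE)
    sentences <- lapply(lens, function(len) {
      toks <- background[sample_zipf(len, cfg$vocab_size, cfg$zipf_alpha)]
      if (cfg$singleton_rate > 0) {
        hit <- which(stats::runif(len) < cfg$singleton_rate)
        for (j in hit) {
          singleton_counter <<- singleton_counter + 1L
          toks[j] <- sprintf("noise%06d", singleton_counter)
        }
      }
      toks
    })
    pos <- which(labels[i, ] == 1L)
    if (length(pos) > 0 && cfg$signal_rate > 0) {
      for (s in seq_along(sentences)) {
        for (p in pos) {
          emit <- signal[[p]][stats::runif(cfg$signal_tokens_per_phenotype) <
                                cfg$signal_rate]
          if (length(emit) > 0) {
            at <- sample(length(sentences[[s]]) + 1L, length(emit),
                         replace = TRUE)
            sentences[[s]] <- insert_tokens(sentences[[s]], emit, at)
          }
        }
      }
    }
    text <- paste(vapply(sentences, paste, "", collapse = " "),
                  collapse = " . ")
    notes[[i]] <- list(id = rownames(labels)[i], sentences = sentences,
                       text = paste0(text, " ."))
    singletons <- c(singletons,
                    unlist(lapply(sentences, function(s)
                      s[startsWith(s, "noise")]), use.names = FALSE))
  }

  categories <- token_categories()
  category_map <- categories[((seq_len(cfg$vocab_size) - 1L) %%
                                length(categories)) + 1L]
  names(category_map) <- background
  sig_tokens <- unlist(signal, use.names = FALSE)
  category_map <- c(category_map,
                    stats::setNames(rep(cfg$signal_category,
                                        length(sig_tokens)), sig_tokens))
  if (length(singletons) > 0)
    category_map <- c(category_map,
                      stats::setNames(rep("others", length(singletons)),
                                      singletons))

  structure(list(notes = notes, labels = labels, category_map = category_map,
                 truth = signal, singleton_tokens = singletons,
                 config = cfg),
            class = "synthetic_corpus")
}

insert_tokens <- function(tokens, new, at) {
  # insert new[k] before position at[k] (positions refer to the original)
  ord <- order(at)
  out <- tokens
  for (k in rev(ord)) out <- append(out, new[k], after = at[k] - 1L)
  out
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("Synthetic corpus: %d notes, %d phenotypes\n",
              length(x$notes), ncol(x$labels)))
  cat(sprintf("  label prevalence: %s\n",
              paste(sprintf("%.2f", colMeans(x$labels)), collapse = " ")))
  cat(sprintf("  %d singleton noise tokens emitted\n",
              length(x$singleton_tokens)))
  invisible(x)
}

#' Permute the phenotype labels of a corpus
#'
#' Rows of the label matrix are permuted jointly across phenotypes, breaking
#' any note-label association while conserving each phenotype's positive
#' count. This is the null model used to calibrate chance-level performance.
#'
#' @param corpus A `synthetic_corpus`.
#' @param seed Integer seed for the permutation, or `NULL` (the identity
#'   sentinel: the corpus is returned unchanged).
#' @return The corpus with permuted labels.
#' @export
permute_labels <- function(corpus, seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (length(corpus$notes) == 0) stop("corpus is empty")
  if (is.null(seed)) return(corpus)
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(corpus$labels))
  labs <- corpus$labels[perm, , drop = FALSE]
  rownames(labs) <- rownames(corpus$labels)
  corpus$labels <- labs
  corpus
}

#' Write / read a corpus as JSONL notes plus a labels CSV
#'
#' Notes are stored one JSON object per line (`id`, `text`, `sentences`);
#' labels as CSV with the note id in the first column; the category map as a
#' two-column TSV and the signal-token truth as JSON.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` returns the
#'   reconstructed `synthetic_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(corpus$notes, function(n)
    jsonlite::toJSON(list(id = n$id, text = n$text, sentences = n$sentences),
                     auto_unbox = TRUE), "")
  writeLines(lines, file.path(dir, "notes.jsonl"))
  labs <- data.frame(note_id = rownames(corpus$labels), corpus$labels,
                     check.names = FALSE)
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.table(
    data.frame(token = names(corpus$category_map),
               category = unname(corpus$category_map)),
    file.path(dir, "categories.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  lines <- readLines(file.path(dir, "notes.jsonl"))
  notes <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(id = x$id,
         sentences = lapply(x$sentences, function(s)
           vapply(s, as.character, "")),
         text = x$text)
  })
  labs <- utils::read.csv(file.path(dir, "labels.csv"), check.names = FALSE)
  labels <- as.matrix(labs[, -1, drop = FALSE])
  storage.mode(labels) <- "integer"
  rownames(labels) <- labs$note_id
  cm <- utils::read.table(file.path(dir, "categories.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  category_map <- stats::setNames(cm$category, cm$token)
  truth <- lapply(jsonlite::read_json(file.path(dir, "truth.json"),
                                      simplifyVector = TRUE), as.character)
  singles <- names(category_map)[startsWith(names(category_map), "noise")]
  structure(list(notes = notes, labels = labels, category_map = category_map,
                 truth = truth, singleton_tokens = singles, config = NULL),
            class = "synthetic_corpus")
}
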