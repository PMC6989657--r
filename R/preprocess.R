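#' Cleanse raw note text
#'
#' Keeps ASCII letters, digits and a configurable set of special characters;
#' every run of other characters (including existing whitespace) collapses to
#' a single space, and leading/trailing space is stripped. The default kept
#' set is `, ( ) ! ? ' .` -- the punctuation that carries structure in
#' clinical notes (periods and commas additionally drive sentence
#' segmentation downstream).
#'
#' @param text Character vector of raw note text (may be empty).
#' @param keep Characters kept besides letters and digits.
#' @return Cleansed character vector of the same length.
#' @export
cleanse <- function(text, keep = c(",", "(", ")", "!", "?", "'", ".")) {
  kept <- paste0("A-Za-z0-9", paste(vapply(keep, esc_char, ""), collapse = ""))
  out <- gsub(paste0("[^", kept, "]+"), " ", text)
  out <- gsub(" +", " ", out)
  trimws(out)
}

esc_char <- function(ch) {
  if (ch %in% c("]", "^", "\\", "-")) paste0("\\", ch) else ch
}

#' Tokenize cleansed text
#'
#' Splits on spaces; kept punctuation characters are emitted as tokens of
#' their own (a token is a word, a number sequence, or a special character).
#'
#' @param clean_text A cleansed string (see [cleanse()]).
#' @param specials Characters emitted as standalone tokens.
#' @return Character vector of tokens (length 0 for empty input).
#' @export
tokenize <- function(clean_text,
                     specials = c(",", "(", ")", "!", "?", "'", ".")) {
  if (length(clean_text) != 1L) stop("tokenize() expects a single string")
  if (!nzchar(clean_text)) return(character(0))
  cls <- paste0("([", paste(vapply(specials, esc_char, ""), collapse = ""), "])")
  padded <- gsub(cls, " \\1 ", clean_text)
  toks <- strsplit(trimws(gsub(" +", " ", padded)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Segment cleansed text into sentences
#'
#' Periods always end a sentence. A comma ends a sentence only when more
#' than `min_comma_span` tokens lie between it and the previous boundary --
#' the heuristic needed because free-form notes often chain long clauses
#' with commas instead of closing them with periods. Boundary characters are
#' not part of the emitted sentences and empty segments are dropped.
#'
#' @param clean_text A cleansed string retaining periods and commas.
#' @param min_comma_span Minimum token span before a comma becomes a
#'   boundary (strictly greater than).
#' @return List of token vectors, one per sentence.
#' @export
segment_sentences <- function(clean_text, min_comma_span = 5L) {
  toks <- tokenize(clean_text)
  sentences <- list()
  current <- character(0)
  for (tok in toks) {
    if (tok == ".") {
      if (length(current) > 0) sentences[[length(sentences) + 1L]] <- current
      current <- character(0)
    } else if (tok == ",") {
      if (length(current) > min_comma_span) {
        sentences[[length(sentences) + 1L]] <- current
        current <- character(0)
      }
      # otherwise the comma is dropped and the clause continues
    } else {
      current <- c(current, tok)
    }
  }
  if (length(current) > 0) sentences[[length(sentences) + 1L]] <- current
  sentences
}

#' Build a token dictionary in first-appearance order
#'
#' Index 1 is reserved for `unk` (tokens unseen at indexing time) and index
#' 2 for `padding`; real tokens receive contiguous indices from 3 in the
#' order of their first appearance in the corpus. With
#' `case_sensitive = FALSE` all tokens are lower-cased before insertion.
#'
#' @param corpus A list of token vectors (or a list of notes, each a list of
#'   sentence token vectors).
#' @param case_sensitive Keep case distinctions?
#' @return A `vocabulary` object.
#' @export
build_vocabulary <- function(corpus, case_sensitive = FALSE) {
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) == 0) stop("corpus is empty")
  if (!case_sensitive) toks <- tolower(toks)
  tokens <- c("unk", "padding", setdiff(unique(toks), c("unk", "padding")))
  structure(list(tokens = tokens, case_sensitive = case_sensitive),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("Vocabulary: %d entries (%d real tokens + unk/padding), %s\n",
              length(x$tokens), length(x$tokens) - 2L,
              if (x$case_sensitive) "case-sensitive" else "case-insensitive"))
  invisible(x)
}

#' @export
length.vocabulary <- function(x) length(x$tokens)

#' Map tokens to dictionary indices
#'
#' @param vocab A [build_vocabulary()] result.
#' @param tokens Character vector; out-of-vocabulary tokens map to 1 (`unk`).
#' @return Integer vector of indices.
#' @export
vocab_lookup <- function(vocab, tokens) {
  if (!vocab$case_sensitive) tokens <- tolower(tokens)
  idx <- match(tokens, vocab$tokens)
  idx[is.na(idx)] <- 1L
  idx
}

#' Reverse-map indices to tokens
#' @param vocab A vocabulary.
#' @param indices Integer indices.
#' @return Character vector of tokens.
#' @export
vocab_tokens <- function(vocab, indices) vocab$tokens[indices]

resolve_overflow <- function(n, max_n, what, overflow) {
  if (n <= max_n) return(n)
  overflow <- match.arg(overflow, c("error", "truncate"))
  if (overflow == "error")
    stop(sprintf("%s has length %d > maximum %d", what, n, max_n))
  warning(sprintf("%s truncated from %d to %d", what, n, max_n))
  max_n
}

#' Index and pad a word-level token sequence
#'
#' @param tokens Character vector of tokens for one note.
#' @param vocab A vocabulary.
#' @param l_max Fixed output length; the suffix is filled with index 2
#'   (`padding`).
#' @param overflow Policy for sequences longer than `l_max`: `"error"`
#'   (default) or `"truncate"` (tail truncation with a warning).
#' @return A `note`: list with `indices` (length `l_max`) and `true_length`.
#' @export
index_and_pad_words <- function(tokens, vocab, l_max,
                                overflow = c("error", "truncate")) {
  n <- resolve_overflow(length(tokens), l_max, "token sequence", overflow)
  idx <- rep(2L, l_max)
  if (n > 0) idx[seq_len(n)] <- vocab_lookup(vocab, tokens[seq_len(n)])
  structure(list(indices = idx, true_length = n), class = "note")
}

#' Index and pad a sentence-structured note
#'
#' Each sentence is right-padded with index 2 to `w_max` tokens and the note
#' is padded with all-`padding` sentences to `s_max`; per-sentence true
#' lengths are recorded so pooling can ignore padding.
#'
#' @param sentences List of token vectors.
#' @param vocab A vocabulary.
#' @param w_max Fixed tokens per sentence.
#' @param s_max Fixed sentences per note.
#' @inheritParams index_and_pad_words
#' @return A `sentence_note`: list with `indices` (`s_max` x `w_max` integer
#'   matrix), `lengths` (per-sentence true lengths) and `n_sentences`.
#' @export
index_and_pad_sentences <- function(sentences, vocab, w_max, s_max,
                                    overflow = c("error", "truncate")) {
  n_sent <- resolve_overflow(length(sentences), s_max, "sentence count",
                             overflow)
  mat <- matrix(2L, nrow = s_max, ncol = w_max)
  lens <- integer(s_max)
  for (s in seq_len(n_sent)) {
    len <- resolve_overflow(length(sentences[[s]]), w_max,
                            sprintf("sentence %d", s), overflow)
    if (len > 0)
      mat[s, seq_len(len)] <- vocab_lookup(vocab, sentences[[s]][seq_len(len)])
    lens[s] <- len
  }
  structure(list(indices = mat, lengths = lens, n_sentences = n_sent),
            class = "sentence_note")
}

#' Convert a corpus to tokenized form
#'
#' Runs the full text pipeline (cleanse, tokenize, segment) on each note's
#' text. Each element of the result carries the word-level token stream
#' (`words`, punctuation included) and the sentence-level token lists
#' (`sentences`, boundary characters excluded). Labels and ids travel as
#' attributes.
#'
#' @param x A `synthetic_corpus`, a character vector of raw texts, or an
#'   existing `token_corpus` (returned unchanged).
#' @param labels Optional label matrix (taken from the corpus if present).
#' @param min_comma_span Passed to [segment_sentences()].
#' @return A `token_corpus`: list of notes, each
#'   `list(words=, sentences=)`, with attributes `ids` and `labels`.
#' @export
as_token_corpus <- function(x, labels = NULL, min_comma_span = 5L) {
  if (inherits(x, "token_corpus")) return(x)
  if (inherits(x, "synthetic_corpus")) {
    texts <- vapply(x$notes, `[[`, "", "text")
    ids <- vapply(x$notes, `[[`, "", "id")
    labels <- x$labels
  } else {
    texts <- as.character(x)
    ids <- if (!is.null(names(texts))) names(texts)
           else sprintf("note_%04d", seq_along(texts))
  }
  notes <- lapply(texts, function(t) {
    clean <- cleanse(t)
    list(words = tokenize(clean),
         sentences = segment_sentences(clean, min_comma_span))
  })
  structure(notes, ids = ids, labels = labels, class = "token_corpus")
}

#' @export
print.token_corpus <- function(x, ...) {
  nw <- vapply(x, function(n) length(n$words), 0L)
  cat(sprintf("Token corpus: %d notes, %d token occurrences (median %d/note)\n",
              length(x), sum(nw), as.integer(stats::median(nw))))
  invisible(x)
}

#' Index and pad a whole corpus for the classifiers
#'
#' Builds (or reuses) a vocabulary and produces the fixed-shape integer
#' inputs both network branches consume. Maximum lengths default to the
#' corpus maxima; `s_max` is additionally raised to `min_s_max` so the
#' sentence-branch filters (up to length 9) always fit.
#'
#' @param corpus A `token_corpus` (or anything [as_token_corpus()] accepts).
#' @param vocab Optional prebuilt vocabulary; built from `corpus` otherwise.
#' @param case_sensitive Used when building the vocabulary.
#' @param l_max,w_max,s_max Fixed dimensions; `NULL` means corpus maximum.
#' @param min_s_max Lower bound applied to `s_max`.
#' @param overflow Overflow policy, see [index_and_pad_words()].
#' @return A `note_set`: list with `word` (n x l_max integer matrix),
#'   `sentence` (list of s_max x w_max matrices), `sentence_lengths`,
#'   `word_lengths`, `ids`, `labels`, and the `vocab`.
#' @export
prepare_notes <- function(corpus, vocab = NULL, case_sensitive = FALSE,
                          l_max = NULL, w_max = NULL, s_max = NULL,
                          min_s_max = 9L,
                          overflow = c("error", "truncate")) {
  corpus <- as_token_corpus(corpus)
  if (is.null(vocab))
    vocab <- build_vocabulary(lapply(corpus, `[[`, "words"), case_sensitive)
  n <- length(corpus)
  wl <- vapply(corpus, function(x) length(x$words), 0L)
  sc <- vapply(corpus, function(x) length(x$sentences), 0L)
  swl <- lapply(corpus, function(x)
    vapply(x$sentences, length, 0L))
  if (is.null(l_max)) l_max <- max(wl, 1L)
  if (is.null(w_max)) w_max <- max(unlist(swl), 1L)
  if (is.null(s_max)) s_max <- max(sc, 1L)
  s_max <- max(s_max, min_s_max)

  word <- matrix(2L, nrow = n, ncol = l_max)
  word_lengths <- integer(n)
  sentence <- vector("list", n)
  sentence_lengths <- vector("list", n)
  for (i in seq_len(n)) {
    nt <- index_and_pad_words(corpus[[i]]$words, vocab, l_max, overflow)
    word[i, ] <- nt$indices
    word_lengths[i] <- nt$true_length
    sn <- index_and_pad_sentences(corpus[[i]]$sentences, vocab, w_max, s_max,
                                  overflow)
    sentence[[i]] <- sn$indices
    sentence_lengths[[i]] <- sn$lengths
  }
  structure(list(word = word, sentence = sentence,
                 sentence_lengths = sentence_lengths,
                 word_lengths = word_lengths,
                 ids = attr(corpus, "ids"), labels = attr(corpus, "labels"),
                 vocab = vocab, l_max = l_max, w_max = w_max, s_max = s_max),
            class = "note_set")
}

#' @export
print.note_set <- function(x, ...) {
  cat(sprintf("Note set: %d notes, L_max %d, %d x %d sentence grid, vocab %d\n",
              nrow(x$word), x$l_max, x$s_max, x$w_max, length(x$vocab)))
  invisible(x)
}

#' Vocabulary serialization (token TAB index)
#' @param vocab A vocabulary.
#' @param path Output TSV path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(token = vocab$tokens, index = seq_along(vocab$tokens)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @param case_sensitive Case flag recorded in the returned vocabulary.
#' @export
read_vocabulary <- function(path, case_sensitive = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  df <- df[order(df$index), ]
  structure(list(tokens = df$token, case_sensitive = case_sensitive),
            class = "vocabulary")
}

#' Serialize indexed notes as JSONL
#'
#' One JSON object per note with fields `id`, `indices`, `sentence_indices`
#' and `lengths`.
#' @param notes A `note_set`.
#' @param path Output path.
#' @export
write_note_set <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes$word)), function(i)
    jsonlite::toJSON(list(id = notes$ids[i],
                          indices = notes$word[i, ],
                          sentence_indices = notes$sentence[[i]],
                          lengths = notes$sentence_lengths[[i]]),
                     auto_unbox = TRUE), "")
  writeLines(lines, path)
  invisible(path)
}
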