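#' Canonical synthetic study corpora
#'
#' Fixed generator configurations used throughout the package's evaluation
#' experiments, scaled so a full cross-validated experiment runs on a single
#' CPU in minutes:
#'
#' * `"strong_signal"`: 500 notes, 4 phenotypes, clearly separable signal
#'   tokens -- the benchmark on which a working classifier should approach
#'   perfect ranking.
#' * `"weak_signal"`: 300 smaller notes with sparser signal than the
#'   benchmark, so sample-size effects (learning curves) remain visible in
#'   the threshold metrics.
#' * `"imbalanced"`: 400 notes at prevalence 0.1 with separable signal --
#'   the regime where unweighted training ranks well but thresholds poorly,
#'   so class-weighted training matters.
#' * `"greedy"`: 240 compact notes, 2 phenotypes, signal confined to the
#'   "symptoms" category -- ground truth for category-prioritization
#'   recovery.
#' * `"zipf"`: a large flat corpus (roughly a million background token
#'   draws, no signal) for rank-frequency exponent recovery.
#'
#' @param kind One of the configurations above.
#' @param seed Integer seed passed to the generator.
#' @return A `synthetic_corpus`.
#' @export
study_corpus <- function(kind = c("strong_signal", "weak_signal",
                                  "imbalanced", "greedy", "zipf"),
                         seed = 1L) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    strong_signal = generator_config(
      n_notes = 500L, n_phenotypes = 4L, vocab_size = 500L,
      signal_tokens_per_phenotype = 5L, signal_rate = 0.3,
      sentences_per_note = c(4L, 9L), words_per_sentence = c(4L, 8L),
      label_prevalences = 0.3, singleton_rate = 0.01, seed = seed),
    weak_signal = generator_config(
      n_notes = 300L, n_phenotypes = 2L, vocab_size = 400L,
      signal_tokens_per_phenotype = 4L, signal_rate = 0.25,
      sentences_per_note = c(3L, 7L), words_per_sentence = c(4L, 8L),
      label_prevalences = 0.35, singleton_rate = 0.01, seed = seed),
    imbalanced = generator_config(
      n_notes = 400L, n_phenotypes = 2L, vocab_size = 400L,
      signal_tokens_per_phenotype = 5L, signal_rate = 0.3,
      sentences_per_note = c(3L, 7L), words_per_sentence = c(4L, 8L),
      label_prevalences = 0.1, singleton_rate = 0.01, seed = seed),
    greedy = generator_config(
      n_notes = 240L, n_phenotypes = 2L, vocab_size = 210L,
      signal_tokens_per_phenotype = 4L, signal_rate = 0.35,
      sentences_per_note = c(3L, 6L), words_per_sentence = c(4L, 8L),
      label_prevalences = 0.4, singleton_rate = 0.01, seed = seed),
    zipf = generator_config(
      n_notes = 1200L, n_phenotypes = 2L, vocab_size = 2000L,
      signal_rate = 0, sentences_per_note = c(80L, 100L),
      words_per_sentence = c(8L, 11L), label_prevalences = 0.3,
      singleton_rate = 0, seed = seed))
  generate_corpus(cfg)
}
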