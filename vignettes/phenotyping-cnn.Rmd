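---
title: "Convolutional patient phenotyping: models, training protocol and token selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional patient phenotyping: models, training protocol and token selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenocnn)
```

# The problem

Patient phenotyping asks whether a patient has (or risks developing) a
specific disorder, judged from free-text clinical notes such as discharge
summaries. The notes are long (thousands of tokens), heterogeneous in style,
full of spelling variants and abbreviations, and each patient can carry
several phenotypes at once, with very uneven class sizes. `phenocnn`
implements a complete experimental stack for this task: text preprocessing,
word embeddings, two convolutional classifiers, cost-sensitive training,
cross-validated evaluation, learning curves, and two token-selection
analyses that probe which tokens actually carry the phenotype information.

Because real clinical corpora are access-controlled, the package ships a
synthetic note generator whose corpora reproduce the statistical structure
those analyses rely on; every claim the test suite makes is a claim about
recovering known properties of that generator.

# Preprocessing

Four steps map raw text to fixed-shape integer inputs.

**Cleansing** keeps ASCII letters, digits and the special characters
`, ( ) ! ? ' .`; every run of other characters (including existing
whitespace) collapses to a single space. **Tokenization** splits on spaces
and emits kept punctuation as standalone tokens, so a token is a word, a
number sequence, or a special character. **Sentence segmentation** ends a
sentence at every period; a comma ends a sentence only when *more than* 5
tokens (configurable, `min_comma_span`) have accumulated since the last
boundary — free-form notes often chain long clauses with commas instead of
closing them. Whether "more than 5" should instead be "5 or more" is
genuinely ambiguous in prose descriptions of such rules; the package uses
the strict reading and exposes the span as a parameter. Boundary characters
are excluded from the emitted sentences but retained as tokens in the
word-level stream, where they were deliberately kept by cleansing.

**Indexing and padding** builds a dictionary in order of first appearance,
with index 1 reserved for `unk` (unseen tokens) and index 2 for `padding`.
Word-level inputs are right-padded with index 2 to a fixed length; sentence
inputs are padded in both dimensions (tokens per sentence, sentences per
note), with per-sentence true lengths recorded so pooling can ignore
padding. Maximum lengths default to the corpus maxima computed on the
training corpus; longer documents at prediction time are tail-truncated
with a warning (the error-vs-truncate policy is an argument). The sentence
dimension is additionally floored at 9 so the longest sentence-branch
filter always fits.

Case handling is a single flag: in case-insensitive mode all tokens are
lower-cased before the dictionary is built. Comparative runs on clinical
data show the two modes performing within each other's standard errors, so
the package defaults to case-insensitive (smaller vocabularies) and leaves
case-sensitive mode one argument away.

# Word embeddings

Tokens enter the networks through a d = 50 dimensional CBOW embedding
(`train_cbow()`), trained with a context window of 10, negative sampling
(10 negatives drawn from the unigram distribution raised to 3/4), 15
iterations, and a minimum count of 5 — tokens rarer than that get no
vector. The implementation is single-threaded stochastic gradient descent
with a linearly decaying learning rate (initial 0.05) and per-position
random window shrinkage, seeded through R's RNG so runs are exactly
reproducible.

`align_to_vocabulary()` turns the raw token→vector map into the
index-aligned table the networks consume: row *i* is the vector of
dictionary index *i*; tokens missing from the map share the `unk` row
(initialized uniformly in ±0.01); the `padding` row is zero and never
contributes to sentence pooling. Embedding training and classification may
use different corpora — embeddings are unsupervised, so they are typically
trained on every note available, not only the annotated subset.

# The classifiers

## Word branch (w-CNN)

An embedded note is an L×d matrix X, one token vector per row. For each
filter length l in the configured set, a group of 100 filters slides along
the temporal axis with stride 1 and no padding; each filter produces the
feature map

  c_i = ReLU(w · x_{i:i+l−1} + b),  i = 1 … L−l+1,

and max-over-time pooling keeps only each map's maximum. The pooled values
concatenate into the feature vector V (one entry per filter), so |V| = 100
× number of filter lengths. Dropout (rate 0.5) is applied to V during
training, and a single sigmoid unit maps it to the positive-class
probability y = Φ(w·V + b). Equivalent formulations with two output
neurons and a normalized pair of scores exist; the single-logit form is
used because it is unambiguous for binary labels and has the same
expressive power.

Per-phenotype filter lengths follow the clinical tuning bundled in
`phenotype_architecture()`: 1–4, 2–5 or 1–5 depending on the disorder.
One disorder (Substance Abuse) is absent from the published length list;
the package groups it with the 2–5 set, which is where the majority of
similar disorders sit.

## Sentence branch and the combined ws-CNN

The sentence branch first pools each sentence's word vectors — sum or
average over the sentence's *true* length, so padding never contributes and
an all-padding sentence pools to the zero vector — giving an S×d matrix of
sentence embeddings. Convolutional groups with filter lengths {1, 5, 7, 9}
and 50 maps each then operate on the sentence sequence exactly as the word
branch does on tokens. The combined model concatenates both branches'
pooled features at the penultimate layer; everything downstream (dropout,
sigmoid) is unchanged. Sum pooling is used for some phenotypes and average
pooling for others (`phenotype_architecture()` records which); on synthetic
data the choice is exposed as the `pooling` argument.

Dropout is applied to the concatenated penultimate vector only — applying
it additionally inside the sentence branch is a possible variant, but the
penultimate site is the conventional one for this architecture family and
is what the package implements.

# Training protocol

`fit_cnn()` trains with:

* **Class-weighted cross-entropy.** Weight 1/n_c per class
  (`compute_class_weights()`), so errors on the minority class cost
  proportionally more. Loss over a batch is the weighted *mean* (batch-sum
  is the other defensible reading; the mean keeps the learning-rate scale
  independent of batch size). Probabilities are clamped to
  [1e−12, 1−1e−12] before the logarithm.
* **Adadelta**, learning-rate multiplier 0.5, batch size 32, 20 epochs.
  The optimizer's decay and epsilon stay at their published defaults
  (ρ = 0.95, ε = 1e−6). Adadelta's effective step size is bounded by
  lr·√ε early in training, so experiments on very small corpora use
  smaller batches (more optimizer steps per epoch) rather than a different
  optimizer; the bundled study configurations note this where they deviate
  from batch 32.
* **Initialization** of all conv and output weights uniform in ±0.01 from
  the training seed.
* **Max-norm projection**: after every optimizer step, any filter weight
  vector with L2 norm above 3 is rescaled to norm 3. The timing
  (per-step projection) is the standard reading of a norm-3 constraint on
  feature-map parameters; biases are not constrained.
* **Selective embedding gradients.** The embedding table is trainable, but
  in the combined model only the word branch back-propagates into it — the
  sentence branch reads the shared table through a detached view. The
  contract is testable: if a token appears only in the sentence-level
  input, its embedding row does not move.
* Training aborts with a diagnostic on non-finite loss, and returns a
  per-epoch train/validation loss trace (the standard overfitting
  diagnostic; at these settings validation loss shows no late-epoch rise).

# Evaluation

Each phenotype is evaluated one-vs-rest. `compute_metrics()` reports
precision, recall, F1 (threshold 0.5, the sigmoid midpoint) and AUROC via
the rank statistic with midrank tie handling — identical to all-pairs
comparison, which the tests verify. `cross_validate()` runs stratified
k-fold CV (default k = 10): the vocabulary and embeddings are built once on
the full corpus (they are unsupervised), while the classifier is retrained
from scratch per fold. Stratification is a package decision: with a few
hundred positives out of ~1600 notes, unstratified folds can lose the
minority class entirely. Summaries report mean ± SE with SE = sd/√k.

`learning_curve()` keeps the test folds fixed and uniformly subsamples each
fold's training split to a fraction x — so the curve isolates training-set
size, and fraction 1.0 reproduces plain cross-validation exactly under the
same seed.

# Token selection

Two mechanisms probe which tokens matter.

**Frequency filtering** removes every token *type* occurring ≤ θ times
(occurrences are deleted, shortening documents — not mapped to `unk`,
since the analysis is re-run on the remaining tokens and re-padded). The
statistical argument: a token seen once can appear in training *or* test
but never both, so it cannot help generalization. Rank-frequency structure
motivates this: `token_frequencies()` and `zipf_fit()` fit
log10(frequency) against log10(rank) by ordinary least squares over a rank
window (default 10–1500), reporting the power-law exponent α = −slope;
clinical-note tokens follow such a Zipf law with α ≈ 0.97, and the
package's generator reproduces a configurable exponent that `zipf_fit()`
recovers within ±0.1. The log base is 10 on both axes (the slope is
base-invariant). `cumulative_fraction()` gives the relative cumulative sum
over the same window.

**Category prioritization** assigns every token to one of seven semantic
categories — symptoms, descriptions, medicine, body, numbers, verbs,
others — and `greedy_category_removal()` removes one category at a time,
always the one whose removal leaves the highest evaluator performance.
Ranks follow the convention that rank 1 = most important: the category
removed at step s gets rank K+1−s, and the never-removed survivor gets
rank 1. This convention is what makes "symptoms is by far the most
important category" coincide with its *low* rank sum across phenotypes.
Ties break by category name order, documented and deterministic. For real
corpora the category map is an input file (manual categorization is not
reconstructible); for synthetic corpora the generator provides it. The
evaluator is a plugged-in function; `cnn_evaluator()` supplies the
standard one (train on a stratified split, score the holdout), defaulting
to F1 with AUROC selectable. The bundled study configuration uses AUROC:
at small problem sizes a barely-trained sigmoid rarely crosses the 0.5
threshold, which degenerates F1 to a constant and turns the greedy choice
into a tie-break; the ranking metric has no such failure mode. Whether
embeddings should be retrained after each removal is an open choice; the
package reuses the pretrained embeddings and retrains only the classifier,
which is cheaper and keeps the comparison between steps controlled.

**Information content.** `information_content()` summarizes a data set by
ψ = N × p_t (sample size × fraction of informative tokens), and
`required_sample_size()` inverts it: matching a reference N′ × p_t′ with
less informative data requires N = ⌈N′ · p_t′ / p_t⌉ samples. On the
clinical corpus the informative fraction runs from 0.39% to 1.21% of
token types, which is why complex architectures gain little at N ≈ 1600.

# The synthetic generator

`generate_corpus()` draws background tokens by inverse-CDF sampling from a
fixed rank table with probability ∝ rank^−α (exact exponent control,
rejection-free), assigns each phenotype label independently at its
configured prevalence, and injects each positive note's signal tokens at a
per-sentence emission rate. Singleton noise tokens — fresh identifiers
that occur exactly once corpus-wide — emulate spelling errors and stray
number sequences. A category map assigns the seven categories round-robin
over background tokens and pins all signal tokens to one configurable
category (default "symptoms"), giving category-prioritization experiments
a known ground truth. Labels are independent across phenotypes: real
comorbidity is correlated, but independence is the simplest model that
still produces multi-phenotype patients.

What the generator does **not** emulate: real clinical vocabulary,
negation ("denies chest pain"), abbreviation ambiguity, section structure,
or correlated comorbidities. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that its mechanisms (class weighting,
token selection, learning curves) behave as designed — not that any
particular performance level transfers to real notes.

Default note shapes (4–10 sentences of 5–12 words) are far shorter than
real discharge summaries (hundreds of sentences averaging ~9 words). The
generator produces paper-scale documents when asked; the defaults keep a
full 10-fold, 20-epoch experiment on one CPU in the minutes range, and
none of the statistical structure the analyses test depends on document
length.

# Bundled study configurations and problem sizes

`study_corpus()` freezes the five corpus configurations used by the test
suite and `scripts/acceptance.R`:

| kind | notes | purpose |
|---|---|---|
| `strong_signal` | 500 | separable benchmark; 10-fold CV of both architectures, permuted-label null, frequency-filter stability |
| `weak_signal` | 300 | learning-curve headroom |
| `imbalanced` | 400, prevalence 0.1 | class-weighting effect on minority recall |
| `greedy` | 240 | category-prioritization recovery |
| `zipf` | ~10^6 tokens | rank-frequency exponent recovery |

Small-corpus experiments (greedy evaluator, learning curve, imbalanced
runs) shrink the batch size to 4–8 so the fixed 20-epoch (or shorter)
budget still supplies Adadelta with enough optimizer steps, and reduce
feature-map counts where full capacity is unnecessary. These sizes are
the package's choice of study condition, stated here so results are
interpretable; all of them are ordinary function arguments.

# Numerical choices and degenerate inputs

* Probabilities are clamped at 1e−12 for the loss; the sigmoid itself is
  evaluated in double precision without clamping.
* `compute_metrics()` defines precision as 1 when nothing is predicted
  positive and flags AUROC as `NA` with a warning on single-class labels.
* Rank ties in `token_frequencies()` break by first appearance (stable
  sort), making ranks deterministic.
* Empty sentences pool to the zero vector; an empty kept-category set
  empties all documents with a warning rather than an error.
* `zipf_fit()` refuses windows with fewer than 3 points.
* All randomness (generator, shuffling, dropout masks, initialization,
  negative sampling, fold assignment) flows through R's RNG from explicit
  seeds; single-threaded runs are bit-reproducible.

# Limitations

* No negation handling, abbreviation expansion, or ontology mapping —
  the pipeline deliberately consumes raw text.
* The CBOW implementation is plain SGD without frequent-word subsampling;
  it targets fidelity to the stated configuration, not throughput on
  billion-token corpora.
* Adadelta at learning rate 0.5 needs hundreds of optimizer steps before
  weights move far; tiny corpora at batch 32 train slowly by design (see
  the training section).
* The greedy procedure retrains the classifier per candidate removal:
  K categories cost K(K+1)/2 − 1 trainings per trace.
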