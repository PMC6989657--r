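# phenocnn

Convolutional patient phenotyping from free-text clinical notes, with the
full experimental stack around the classifiers: preprocessing, CBOW word
embeddings, cost-sensitive training, cross-validated evaluation, learning
curves, Zipf rank-frequency analysis and token-selection experiments.

## Who this is for

Researchers studying automatic phenotype prediction from electronic health
record text — e.g. deciding from a discharge summary whether a patient has
advanced cancer, chronic pain, depression, or any of a set of disorders —
and, more broadly, anyone who wants a reproducible, dependency-light R
implementation of word/sentence-level convolutional text classification
with class-weighted training. Real clinical corpora are access-controlled,
so the package bundles a synthetic note generator that reproduces the
statistical structure the analyses rely on (Zipf-distributed vocabulary,
sentence-structured documents, once-only noise tokens, category-tagged
signal tokens, uneven multi-label classes); every pipeline stage is
testable against that generator's known ground truth.

## The models

A note is embedded as an L×d matrix X (one d = 50 token vector per row,
from CBOW embeddings). The **w-CNN** applies groups of 100 convolutional
filters per filter length l (stride 1, no padding),

    c_i = ReLU(w · x_{i:i+l−1} + b),   i = 1 … L−l+1,

max-over-time pools each feature map to a single value, concatenates the
pooled values into a feature vector V, applies dropout (0.5), and scores
y = Φ(w·V + b) with a sigmoid Φ. The **ws-CNN** adds a sentence branch:
each sentence's word vectors are pooled (sum or average over the true
sentence length; padding never contributes) into a sentence embedding, a
second set of conv groups (lengths {1,5,7,9}, 50 maps) runs over the
sentence sequence, and both branches concatenate at the penultimate layer.

Training is cost-sensitive: cross-entropy weighted by 1/n_c per class,
Adadelta (lr 0.5), batches of 32, 20 epochs, uniform ±0.01 initialization,
max-norm 3 projection of every filter after each step. Embeddings stay
trainable, but only word-branch gradients update them. Evaluation is
one-vs-rest stratified k-fold cross-validation reporting precision,
recall, F1 and AUROC as mean ± SE (sd/√k).

Token-selection analyses ask *which* tokens carry the signal: frequency
filtering removes token types occurring ≤ θ times; greedy category
prioritization removes one of seven semantic categories at a time, always
the one costing the least performance, yielding an importance ranking
(rank 1 = survives longest); `zipf_fit()` measures the rank-frequency
power-law exponent; and ψ = N × p_t summarizes data-set information
content (sample size × informative-token fraction).

## Worked example

```r
library(phenocnn)

corpus <- generate_corpus(generator_config(n_notes = 200, n_phenotypes = 2,
  vocab_size = 300, signal_rate = 0.3, seed = 42))
corpus
#> Synthetic corpus: 200 notes, 2 phenotypes
#>   label prevalence: 0.26 0.23
#>   138 singleton noise tokens emitted

# rank-frequency structure of the generated vocabulary
tab <- token_frequencies(as_token_corpus(corpus))
zipf_fit(tab, rank_lo = 10, rank_hi = 250)
#> Zipf fit over ranks 10-250: alpha = 1.072 (R^2 = 0.976)

# cross-validated w-CNN for one phenotype
cv <- cross_validate(corpus, "phenotype_01",
  model_args = list(filter_lengths = 1:4),
  train_config = train_config(epochs = 10, seed = 1),
  embedding_config = embedding_config(seed = 42),
  k = 5, seed = 7)
cv
#> 5-fold cross-validation
#>   precision  54.24% +- 13.78%
#>   recall    100.00% +- 0.00%
#>   f1         66.31% +- 11.37%
#>   auroc     100.00% +- 0.00%
```

The AUROC of 100% says the classifier ranks every positive above every
negative — the generator's signal tokens are clearly separable at this
emission rate. The lower precision reflects the 0.5 decision threshold
combined with 1/n_c class weighting, which deliberately trades false
positives for minority-class recall; that trade-off is exactly what the
class-weighting experiment measures.

A command-line driver wraps the same functions
(`system.file("cli", "phenocnn.R", package = "phenocnn")`):

```sh
Rscript phenocnn.R generate --seed 7 --n_notes 200 --out corpus/
Rscript phenocnn.R evaluate --corpus corpus/ --phenotype phenotype_01 --k 10 --out results/
Rscript phenocnn.R zipf --corpus corpus/ --out results/
```

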