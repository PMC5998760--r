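---
title: "Semi-supervised bi-LSTM tagging of adverse drug reaction mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised bi-LSTM tagging of adverse drug reaction mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adverse drug reactions (ADRs) are widely under-reported through formal
pharmacovigilance channels, while social media carries a large volume of
first-person reports ("this effexor is not making me feel so awesome").
Extracting the text spans that describe an ADR is a sequence-labeling
problem on short, noisy text: URLs, user handles, hashtags, emoticons,
creative spelling. The practical obstacle is labeled-data scarcity —
per-token span annotation is expensive, so labeled corpora are a few
hundred documents, far too small for a recurrent network with millions of
parameters.

`adrtag` implements a two-phase semi-supervised remedy built around one
shared bidirectional LSTM encoder:

1. **Unsupervised phase.** From a large unlabeled corpus, keep the
   documents that mention exactly one drug (located with a curated
   drug-name lexicon), replace the mention with a dummy token `<DRUG>`,
   and train the encoder (with an average-pooled softmax head) to predict
   *which* drug was masked from its context alone. Masking prevents the
   degenerate copy solution, so the network is forced to model drug
   context — which is where ADR mentions live.
2. **Supervised phase.** Transfer every encoder weight (embeddings,
   recurrent and projection matrices) into a per-token tagger with a fresh
   softmax head over the IO tag set `{I-ADR, I-Indication, O, <PAD>}`, and
   fine-tune everything on the small labeled corpus.

Evaluation uses approximate span matching: a predicted span counts as
correct if it overlaps at least one gold span of the same label (with gold
"sleep paralysis", both "lasting sleep paralysis" and bare "paralysis"
count). Precision, recall and F1 are micro-aggregated over the corpus, and
headline numbers are reported for the ADR label only, since Indication
annotations are rare.

## Model

Each direction of the encoder is a standard LSTM. With input vector
$x_t$, previous hidden state $h_{t-1}$ and memory cell $m_{t-1}$:

$$
\begin{aligned}
g^u &= \sigma(W^u h_{t-1} + I^u x_t + b^u), \quad
g^f = \sigma(W^f h_{t-1} + I^f x_t + b^f), \\
g^o &= \sigma(W^o h_{t-1} + I^o x_t + b^o), \quad
g^c = \tanh(W^c h_{t-1} + I^c x_t + b^c), \\
m_t &= g^f \odot m_{t-1} + g^u \odot g^c, \qquad
h_t = g^o \odot \tanh(m_t).
\end{aligned}
$$

The per-token representation is the concatenation
$\mathbf h_t = [\vec h_t ; \overleftarrow h_t]$ of the two directions. For
the drug-prediction head the sequence is average-pooled over non-padding
steps and passed through a softmax over the drug vocabulary; for the
tagging head a softmax $y_t = \mathrm{softmax}(W \mathbf h_t + b)$ is
applied at every step and the loss is the summed categorical cross-entropy
over non-padding steps. The implementation's backward pass is exact
backpropagation through time, verified against central finite differences
(`test-gradients.R`).

Two places where published descriptions of this architecture family are
internally inconsistent required a decision:

* The memory-cell update is sometimes printed without the $m_{t-1}$ term
  and with the output squashing misplaced, which would leave the memory
  cell unable to propagate; this package implements the standard update
  shown above.
* The pooled representation is described as average-pooling but printed as
  a plain sum. The text reading (mean over non-padding steps) is the
  default; `model_config(pool = "sum")` restores the literal formula.

## Preprocessing and encoding

Normalization replaces URLs with `<LINK>` and user handles with `<USER>`,
removes punctuation and `#`, drops non-ASCII characters (emoticons),
lower-cases, and collapses whitespace. Tokenization is whitespace
splitting of the normalized text; the same tokenizer is applied to the
drug lexicon, so multi-word names ("zoledronic acid") match as token
subsequences — case-insensitively, exactly, longest-match first, left to
right. "Exactly one mention" is read strictly: the same drug twice is two
mentions and the document is dropped from pretraining.

The same normalization is applied to the labeled and the unlabeled corpus.
Annotations arrive as character offsets into the *raw* text, so the
normalizer records for every surviving token the raw-character interval it
came from; a token belongs to an annotation iff the intervals overlap.
Runs of same-label tokens become entity spans, ADR winning when labels
collide on a token (ADR is the evaluated class). IO encoding cannot
separate adjacent same-label mentions — an accepted property of the
scheme, not a bug.

The vocabulary pools labeled and unlabeled corpora, drops stopwords (a
standard English list shipped with the package, applied to vocabulary
membership only — tokens are never deleted from sequences), and keeps the
15000 most frequent tokens by default, ties broken lexicographically.
Sequences are padded (index 0) or truncated to `max_len`, which defaults
to the 95th percentile of training-corpus lengths rather than a hard-coded
platform-era constant.

## Training

Defaults mirror the published protocol: adam (learning rate 0.001, the
optimizer default, as no rate is stated) with mini-batches of 128 for 30
epochs in the unsupervised phase, and per-example updates (batch size 1)
for 5 epochs in the supervised phase. Per-epoch shuffling and all weight
initialization (Glorot-uniform, forget-gate bias 1) derive from a single
integer seed, making runs bitwise-reproducible on one thread. Two
deliberate additions where the protocol is silent: gradients are clipped
to global norm 5 to stabilize batch-size-1 updates, and the `<PAD>`
embedding row is pinned at zero (its gradient is projected out). The
embedding matrix is trainable in both phases by default
(`model_config(train_embeddings = FALSE)` freezes it). Embeddings can be
initialized from a word2vec text or binary file; vocabulary tokens missing
from the file fall back to uniform(−0.05, 0.05) draws.

Decoding restricts real tokens to the three content tags; the `<PAD>`
category describes padding positions only.

## The synthetic benchmark

The original study's corpus cannot be redistributed (tweet identifiers
only), so the package ships a seeded generator that emulates its
statistical structure at desk scale. Every generated document contains
exactly one drug mention (pronounceable pseudo-names, one in ten
multi-token); context words come from a drug-specific private pool with
probability `context_signal` (default 0.8) and from a shared pool
otherwise; URL / user-mention / emoticon / typo / punctuation noise is
injected at configurable rates. ADR phrases (1–4 tokens) and Indication
phrases are compositional draws from drug-conditioned word pools rather
than a fixed phrase list, so a tagger cannot simply memorize phrases, and
labeled and unlabeled documents follow the *same* distribution — unlabeled
text simply lacks annotations — so pretraining sees the vocabulary and
phrase structure the tagger is later scored on. A further realistic
confound ties tags to the drug: other drugs' ADR words may occur scattered
as ordinary context (tagged O), the way a symptom term is only an adverse
reaction when it is attributable to the mentioned drug, so perfect tagging
of unseen words requires the drug–symptom pairing that only the unlabeled
corpus exhibits in volume.

Desk-scale defaults — 10 drugs, 2000 unlabeled documents, 150 labeled
(100 train / 50 test in the benchmark), shared vocabulary of 150 words
plus per-drug pools of 5 context + 25 ADR + 3 Indication words, mean
document length 9 content words — keep the full pipeline within minutes on
one CPU. What the generator does *not* emulate: real lexical semantics,
misspelled drug names (lexicon matching is exact by scope), code-switching
and sarcasm, annotation disagreement. Passing tests on this benchmark
therefore demonstrate that the machinery is correct and that the pipeline
can exploit the planted structure; they are not evidence about
performance on real social-media text.

The benchmark model is scaled to the data (32-dimensional embeddings, 32
hidden units per direction; the full-scale defaults of 400/500 remain the
package defaults). Pretraining runs 10 epochs — the synthetic pretext task
converges well within that — and fine-tuning runs 20 epochs for both arms,
so that the number of batch-size-1 updates on 100 labeled documents
(2000) roughly matches the original 5-epoch protocol on its larger
labeled corpus (2350).

```r
library(adrtag)
bm <- run_transfer_benchmark(n_seeds = 10)
bm
```

`run_transfer_benchmark()` fixes one generated corpus and varies the
training seed only (initialization and shuffling), mirroring the
repeated-trial protocol of the original comparison, then reports the mean
test F1 of the pretrained and from-scratch arms with a paired t-test.

## Numerical and degenerate-input choices

* Softmax is computed with the row-max subtracted; all outputs are
  simplex-valued to 1e-6.
* Zero predicted spans define precision 0 (with a warning), zero gold
  spans define recall 0; F1 is 0 when P + R = 0.
* The paired t-test handles zero-variance differences explicitly:
  identical inputs give t = 0, p = 1; a constant non-zero difference is
  reported as t = ±Inf, p = 0.
* Precision's numerator counts predicted spans overlapping any gold span;
  `precision_numerator = "unique_gold"` switches to counting distinct gold
  spans hit (both conventions are tested against a brute-force counter).
* An all-padding sequence cannot be pooled (error); masking a document
  with zero or several drug spans is an error — callers filter first.
* Annotations that overlap no token after normalization are dropped with a
  warning; tokens beyond the truncation length are dropped with a warning.

## Known limitations

Fine-tuning from the pretrained encoder is *not* guaranteed to beat
training from scratch on this synthetic benchmark; at desk scale the two
arms are typically statistically tied (run `run_transfer_benchmark()` to
compute the comparison). The mechanism behind the weak effect: the pooled
drug-classification objective organizes the *embedding* space as intended
(words from the same drug's vocabulary cluster together), but it
simultaneously pushes the *recurrent* dynamics toward document-level
drug-identity representations, which carry little per-token information —
the tagging head needs token-level distinctions that the pretext task
never rewards. Transferring the full encoder therefore starts fine-tuning
from a point that fits the training set but generalizes no better than a
fresh initialization. The benchmark reports the comparison with a paired
t-test rather than assuming its direction. A pretext objective with a
per-token loss (e.g. masked-token prediction at every position) would
likely transfer better, but lies outside this package's scope.

Other limitations: exact lexicon matching misses misspelled drug names by
design; IO encoding merges adjacent same-label mentions; no CRF layer, so
predicted spans have no transition consistency beyond what the encoder
learns; pure-R training is practical at benchmark scale but slow at the
full 400/500 configuration on large corpora.
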