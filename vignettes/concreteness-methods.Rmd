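---
title: "Methods: automated concreteness rating with dual embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated concreteness rating with dual embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concretr)
```

# The model and its assumptions

Human concreteness norms place every expression on a 1–5 Likert scale
(1 = highly abstract, 5 = highly concrete). `concretr` predicts that
rating from a **dual embedding**: a 512-d base text embedding carrying
visual–linguistic grounding concatenated with a 512-d emotion-aware
embedding, giving a 1024-d feature (base half first — the order is part
of the contract and is tested). The working assumption is the standard
grounding account: concrete meanings lean on sensory–perceptual
information, abstract meanings on emotional and introspective
information, so the two embedding views are complementary and their
concatenation is more informative than either half.

The regressor is deliberately small: 1024 → 128 → 64 → 1 with ReLU hidden
activations, dropout 0.2 after each hidden layer, and a linear output
(139,521 parameters). Its output is reported both raw and clamped to
[1, 5]; clamping is a reporting convention, not part of training.

The emotion-aware encoder is produced by contrastive fine-tuning: both
encoder towers and the temperature are updated (no layer freezing) to
minimize the symmetric cross-entropy over the temperature-scaled
cosine-similarity matrix of an image–label batch, matched pairs on the
diagonal. Closed forms pin the implementation down: a single-pair batch
has loss exactly 0, a batch of N identical embeddings exactly ln N, and
the analytic gradients agree with numerical differentiation (tested to
1e-5).

# Training regime

Training minimizes MSE with Adam at initial learning rate 5e-4, batch
size 50 with per-epoch shuffling, L2 weight decay 1e-5, a
reduce-on-plateau scheduler (factor 0.1, patience 3), early stopping
(patience 5) monitored on a 10 % validation split stratified at the 2.88
concrete/abstract boundary, and seed 42 for every random choice. The
weights returned are those of the best-validation epoch, which is what
makes the best-epoch contract (validation MSE at the returned weights is
the minimum of the recorded history) testable.

Choices the regime leaves open, fixed here:

* **Maximum epochs: 100.** No canonical value exists; with early stopping
  at patience 5 the bound is rarely reached.
* **Scheduler improvement threshold: absolute decrease of 1e-4.** Smaller
  decreases count as a plateau. Fixed for reproducibility.
* **Initialization: uniform fan-in, output bias at 3.** Weights and
  biases draw from U(−1/√fan_in, 1/√fan_in); the output-layer bias starts
  at the Likert midpoint 3. This is the usual regression-head practice of
  starting the head at the target scale's centre. It matters at small n:
  with ~36 optimizer steps per epoch, a head starting at 0 spends most of
  its budget climbing to the rating mean while the plateau scheduler and
  early stopping run down, so training dies long before convergence.
* **Validation split stratified at 2.88**, mirroring the main split, with
  the boundary value itself counted as concrete.
* **Prediction confidence** is not defined by the architecture; the
  package uses Monte-Carlo dropout: confidence = 1/(1 + SD of 20
  stochastic forward passes), deterministic given a seed. It is the
  tie-breaker for compound-word disagreement resolution and the stand-in
  for out-of-distribution detection.

# The prediction system

Inputs are normalized (lowercase, trimmed, whitespace collapsed), cleaned
(articles *a/an/the* and conjunctions *and/or/but* removed as whole
tokens only; trailing ellipsis periods truncated; typographic punctuation
mapped to ASCII), and classified by token count: one token → single-word
model, several → multi-word model, with hyphenated compounds kept as one
token. A hyphenated compound is also parseable as two words, so it is
scored by both models and the higher-confidence prediction wins
(ties → single-word model). Sentences — flagged by the caller, ending in
sentence punctuation with ≥ 3 tokens, or longer than ten words — are
rated per content word; in contextual mode word features come from the
backends' context-sensitive embedding of the word within the sentence, in
standalone mode from the bare word (the same word then scores identically
in any sentence). Both modes ship because no single mechanism for
context-sensitivity is canonical; contextual is the default.

Non-English input is detected (pluggable detector; the built-in one is a
small stopword/diacritic heuristic with a 0.90 confidence threshold) and
translated through an adapter contract (beam size 5, maximum length 128,
forced-English target). Translations are verified by character-length
ratio (within [0.2, 5]), character-set check, and embedding cosine
similarity (≥ 0.2); among passing candidates the most source-similar wins,
ties by beam rank, and when none pass the top-beam candidate is used and
flagged for review. Empty candidate lists fall back to the source text.
English input never enters the translation path. Items that fail anywhere
degrade to the fallback score — the single-word training mean stored in
the bundle, a more defensible "average" than the scale midpoint — and are
flagged; no input is ever dropped.

# Synthetic data: what it emulates, and what passing tests show

Every fixture is generated in code:

* **Rating corpora** (`gen_corpus`): pronounceable pseudo-word
  expressions with mean ratings drawn from an equal-weight Gaussian
  mixture at 2.5 and 4.5 (component SD 0.6) truncated to [1, 5] — the
  characteristic bimodal shape of human concreteness norms, with overall
  mean near 3.5 and SD near 1.1.
* **Rater tables** (`gen_raters`): each rater's rating is the
  expression's true score plus Gaussian noise, clamped to [1, 5]. The
  expected Spearman–Brown-corrected split-half reliability and
  single-rating ICC are computed in closed form from clamped-normal
  moments — the truncation is accounted for, which is why the recovery
  tests can use a 0.02 tolerance honestly. The naive
  var(T)/(var(T)+σ²) ratio is also stored as the no-clamp limit.
* **Planted-signal backends** (`make_planted_backend`): a token's vector
  is a seeded unit pseudo-random 512-d carrier plus a planted signal
  along fixed directions. Three hashed standard-normal components u, v, w
  define the token's latent score clamp(3 + 0.8·(u+v+w)/√3, 1, 5) — an
  affine function of the planted components, so the regression target is
  a noiseless deterministic function of the feature. The base backend
  encodes u and w, the emotion backend v and w: partially disjoint
  directions, so either half alone sees two thirds of the latent variance
  (ceiling r ≈ √(2/3) ≈ 0.82) while the concatenation sees all of it.
  The default signal strength is 4 (signal four times the unit-norm
  carrier): in that regime latent recovery is a property of the
  construction rather than of optimizer luck, which is what the recovery
  guarantee (held-out r ≥ 0.99, MAE ≤ 0.05 at n = 2000 under the exact
  training regime above) is meant to probe.
* **Image–label pairs** (`gen_image_text_pairs`): 16×16 images whose
  pixels are a label-keyed pattern plus small noise, so contrastive
  alignment is learnable by the toy two-tower encoder.

What passing tests do **not** show: real embeddings are not unit noise
plus a linear planted signal; real rater noise is neither Gaussian nor
homoscedastic; pseudo-words carry no frequency, length or morphology
effects; and the translation/detection doubles are deterministic. The
synthetic results validate the machinery — estimators against their
closed forms, the training loop against recoverable signal, the pipeline
against its contracts — not performance on real norms.

# Numerical choices and degenerate inputs

* Standardization uses population SDs; zero-variance dimensions get scale
  1 so they transform to exact zeros instead of dividing by zero.
* R² is 1 − SSres/SStot (variance explained), deliberately not the
  squared correlation: a well-correlated but biased predictor separates
  the two. Zero variance in the true scores is an error, not an NaN.
* Confidence intervals for r use Fisher's z at 95 %; p-values come from
  t = r·√((n−2)/(1−r²)), two-tailed.
* Split-half bipartitions of an odd rater count use sizes ⌊n/2⌋ and
  ⌈n/2⌉; iterations with fewer than three common expressions are skipped
  with a warning, and all-skipped is an error. Rater IDs are sorted
  internally so the estimate is invariant to row order and relabeling.
* The ICC is the standard one-way random-effects form — random intercept
  per expression, ICC = between/(between+within) — fitted with lme4. (A
  literal "random intercept with expression as a fixed effect" does not
  yield an ICC; the random-grouping reading is the only coherent one.)
* High-disagreement exclusion is a single pass: the mean and SD of the
  rating SDs are computed once on the input, and records more than k = 3
  SDs above the mean are removed. Iterating to convergence would be a
  different (trimming) procedure.
* Duplicate expressions after normalization keep their first occurrence;
  determinism of splits and caching depends on it.
* Stratified splitting allocates round(test_n · stratum share) to the
  concrete stratum; the concrete fraction of the test set therefore
  matches the corpus within 1/test_n exactly.

# Problem sizes

The validation suite runs at sizes chosen to make each property sharp but
cheap: regressor recovery at n = 2000 embeddings (1600 train / 400 test),
the combined-versus-single comparison at n = 1200, split-half recovery at
500 expressions × 40 raters with 100 iterations, ICC recovery at 300 × 20
over 20 seeds, and oracle-equivalence checks on 100 random instances per
statistic. The bookkeeping check of the 36,058/1,000 stratified split
runs at the full 37,058.

# Known limitations

The package ships no pretrained encoders or real norm corpora; with the
synthetic backends it validates machinery, not linguistic performance.
Language detection is a small heuristic unless a stronger detector is
plugged in; "language-specific preprocessing" beyond the documented
cleaning rules is not implemented. Translation quality is entirely the
adapter's. Sentence-mode context sensitivity depends on the backend
exposing contextual embeddings; the fallback is the bare-word embedding.
The regressor's architecture and hyperparameters are fixed by design —
no search is provided.
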