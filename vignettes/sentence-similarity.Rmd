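---
title: "Methods: sentence similarity scoring, combination and evaluation"
author: "sentsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentence similarity scoring, combination and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sentsim)
```

`sentsim` estimates how similar two sentences from the biomedical
literature are in meaning, on the continuous 0–4 scale used by
expert-annotated sentence-pair benchmarks. This vignette explains the
models and procedures, the parameters that matter, the numerical
choices, and what the package's synthetic fixtures do and do not show
about real data.

## The task and the pipeline

Semantic textual similarity is evaluated intrinsically: a scoring
function maps a sentence pair to a number, and its quality is the
correlation (Pearson *r*, Spearman *r*ₛ) between its scores and
averaged human judgments over a benchmark of pairs. The pipeline has
four stages: corpus preparation, per-pair scoring by several metrics,
combination of the per-pair scores, and evaluation.

## Corpus preparation

The embedding-training corpus is one sentence per line. Three
heuristics shape it:

* **Long-line filtering** (`filter_long_lines()`). Full-text article
  dumps contain non-prose lines — large numeric tables, supplementary
  listings — that are very long and slow down or degrade embedding
  training. Lines are kept only when *strictly shorter* than
  `max_line_chars` (default 200 characters): a 199-character line is
  kept, a 200-character line is removed. The filter is idempotent.
* **Hyphen-compound splitting** (`split_hyphens()`). Biomedical prose
  is dense in hyphenated compounds (`anti-HER2`, `knock-down`) whose
  parts are informative on their own. A hyphen is replaced by a space
  only between two alphanumeric neighbours; leading and trailing
  hyphens are stripped. This preserves every non-hyphen character and
  never touches tokens such as negative numbers in isolation.
* **Stopword and punctuation removal** (`remove_stopwords()`), applied
  inside the *string-based* scorers only. The stopword list is data,
  not code: it is injected through `preprocess_config()` because the
  choice of list (the packaged default has about 150 entries) visibly
  shifts string-metric scores. The punctuation set defaults to the
  eight marks full stop, comma, colon, semicolon, question mark,
  exclamation mark, slash and dash. Embedding-style scorers keep
  function words, since embedding models are trained with them.

Sentence segmentation is a deterministic rule: a boundary is terminal
punctuation followed by whitespace and an upper-case letter, digit or
opening quote, unless the preceding token is a protected abbreviation
(`e.g`, `fig`, `et al`, single initials, ...). The rule set is
deliberately small — it is transparent and testable, and any external
segmenter can be swapped in wherever a sentence vector is accepted,
since all downstream functions take plain character vectors. The
pipeline order is segmentation → tokenization → post-processing
(hyphen splitting, filtering, optional stopword removal); the exact
interleaving of hyphen splitting is a genuine design freedom and this
order was fixed once so that the corpus and the scorers see identical
text.

## String-based metrics

The **Jaccard index** operates on the *unique* tokens of the two
preprocessed sentences: J(A, B) = |A ∩ B| / |A ∪ B|. It is symmetric
and invariant to token order and duplication. When both sets are empty
the ratio is 0/0; the package defines the score as 0 and warns, and the
evaluation layer treats a failed score as missing rather than imputing.

The **q-gram similarity** counts contiguous character substrings of
length q. Two conventions needed fixing where the definition leaves
room:

* *Items are characters, q = 3 by default.* q-gram items can in
  principle be letters or words; the character-trigram convention is
  the standard one for this family of measures and is the package
  default (word-level grams are available by tokenizing upstream).
* *Asymmetry.* The definition divides the number of q-gram matches by
  the number of q-grams of the *first* string, so the measure is
  directional. The package computes it as written, with sentence 1 of
  a pair as the reference; `symmetrize = "mean"` averages the two
  directions for callers who want a symmetric score. Matches are
  counted as a multiset intersection — each gram occurrence matches at
  most once — which is the standard q-gram-distance convention.
* *No padding.* Profiles are empty for strings shorter than q, giving
  a 0 score with a warning rather than an error.

Strings fed to q-gram scoring are the stopword-stripped, case-folded
sentences re-joined with single spaces, so both string metrics see the
same text.

## Embedding backends

Two contracts cover the embedding world:

* `word_vector_table` — per-token vectors; a sentence vector is an
  element-wise **pooling** (max, min, sum or mean) of its in-vocabulary
  token vectors. Mean pooling equals sum pooling scaled by 1/n, so the
  two give identical cosine scores; both are kept because downstream
  consumers other than cosine may care. Max pooling is the documented
  default for word tables, reflecting that max-pooled word vectors are
  the strongest configuration of this family on expert-annotated
  benchmarks.
* `sentence_encoder` — an opaque deterministic function from tokens to
  a fixed-length vector, the adapter for externally trained
  whole-sentence models (paragraph-vector variants, sent2vec-style
  models, RNN encoders). These are loaded and applied, never retrained
  here: training such models is only meaningful at full-corpus scale.

Similarity of two sentence vectors is the **cosine** of their angle.
A zero vector has no direction, so the cosine errors rather than
returning a number; the evaluation layer converts that into a flagged
missing score. **Out-of-vocabulary policy:** OOV tokens are skipped
when pooling and their count is reported (`oov_count`); only a
sentence with *no* in-vocabulary token fails. Skipping is preferred
over zero-filling because zero vectors silently drag pooled means
toward the origin.

### The built-in trainer

`train_word_table()` implements a count-based distributional embedding:
a symmetric token co-occurrence matrix over a sliding window (default
5), re-weighted by positive pointwise mutual information (PPMI), then
factored by a truncated SVD, with token i embedded as row i of
U_d √Σ_d. This estimator is a classical member of the word-embedding
family with well-understood behaviour, and it has a property that
matters for a test harness: it is *fully deterministic* — no stochastic
gradient descent, no negative sampling, no thread-order noise. Two
runs on the same corpus give byte-identical tables (singular-vector
signs are fixed by making each column's largest-magnitude loading
positive). The `min_count` threshold (default 5) drops rare tokens
entirely: the vocabulary covers exactly the tokens reaching the
threshold. Predictive models (skip-gram, CBOW) plug in through the
word2vec-format reader instead. The dense SVD bounds the practical
vocabulary at a few thousand types, which is ample at desk scale and
irrelevant for externally trained tables.

## Combining scores

The **unsupervised hybrid** is the arithmetic mean of the per-pair
scores of several metrics, string-based scores entering unchanged
alongside cosines — they are all similarity scores on comparable
[0, 1]-ish scales, and taking them at face value is the only coherent
reading of a plain average.

The **supervised combiner** is unregularized ordinary least squares,
y = b₀ + Σⱼ bⱼ xⱼ, fit by QR decomposition; a rank-deficient design
errors with the names of the collinear features rather than silently
dropping one. Because the evaluation protocol for a supervised
combiner on a 100-pair benchmark is genuinely ambiguous (in-sample fit
vs held-out prediction differ, and small benchmarks make the
difference material), `fit_combiner()` reports **both**: the in-sample
Pearson *r*, and a k-fold cross-validated *r* (default 10 folds, fold
assignment fixed by a seed), always labelled separately. In-sample OLS
*r* is mathematically at least the best single feature's |r|, which
the test suite asserts as an optimality property.

Two named feature presets (`combiner_presets()`) record the
conventional configurations: a six-feature supervised set (Jaccard,
q-gram, and four encoder cosines) and a four-feature hybrid-mean set.
They are column-name conventions for feature tables; any encoder
satisfying the adapter contracts can stand behind a name.

## Evaluation harness

Benchmarks are TSV files with header `pair_id`, `sentence1`,
`sentence2`, `score`, `subset`; gold scores must parse as numbers in
[0, 4] and a malformed row errors with its row number. Both Pearson
and Spearman correlations are always computed; reports headline
Pearson, with Spearman retained in the object, mirroring the common
reporting convention for this task (the two rarely diverge on graded
similarity). Pairs the scorer cannot handle are excluded from the
correlation and counted — never imputed as 0, which would distort *r*
unpredictably — and a report in which more than half the pairs are
missing is refused outright.

The **high-similarity subset** is selected by gold ≥ 3.5, inclusive:
a pair rated exactly 3.5 belongs to the subset.

### Contradiction probe

Negation ("X was reported **to not** interact ...") and antonym
substitution (induces → inhibits) flip a sentence's meaning while
leaving nearly all tokens intact. The probe computes, per scorer, the
mean predicted similarity on each subset, and flags whether the
expected ordering — highly similar pairs above contradiction pairs —
holds. For lexical-overlap scorers (and for embedding models that
average context) it typically does not: contradiction pairs share
almost all their tokens, while genuinely similar paraphrase pairs
share only part of their wording. No significance test is attached:
with subsets of 7–13 pairs such a test would have almost no power, so
only the direction of the effect is reported.

## The synthetic-fixture generator

`fixture_config()` fixes the desk-scale study conditions once:

| parameter | default | what it emulates |
|---|---|---|
| `n_sentences` | 5000 | corpus large enough for stable co-occurrence statistics at desk scale |
| `vocab_size` / `n_topics` | 600 / 6 | topical co-occurrence structure that embeddings should recover |
| `benchmark_size` | 100 | the canonical benchmark size for this task |
| `overlap_noise` | 0.25 | annotator disagreement around the construction `gold = 4·overlap` |
| `fraction_long_lines` | 0.02 | table-like non-prose contamination (lines ≥ 200 chars) |
| `fraction_hyphenated` | 0.1 | hyphenated-compound density of biomedical prose |

Contradiction fixtures default to 13 negation and 7 antonym pairs with
an 11-pair high-similarity reference, so report shapes match the
conventional presentation of this analysis.

Benchmark pairs are built with controlled unique-token overlap
spanning [0, 1]: sentence 2 shares a set fraction of sentence 1's
tokens and fills the rest from a *different* topic, so lexical overlap
and topical relatedness move together, as they do in citation-derived
benchmarks. Gold is 4·overlap plus Gaussian annotator noise, clipped
to [0, 4]. At zero noise this makes the Jaccard score *identically*
proportional to gold — a construction identity the acceptance tests
exploit (r = 1 to 1e−6) — and the noise default of 0.25 was chosen
once as a plausible annotator standard deviation on a 0–4 scale.

The probe's high-similarity reference uses a *separate* generator
(`generate_similar_pairs()`): pairs with gold in [3.5, 4] but only
moderate token overlap (Jaccard ≈ 0.33–0.6). This reflects the
paraphrase regime of real expert-rated similar pairs — two sentences
can mean the same thing with different words — and it is what makes
the probe informative: in the main benchmark's lexical regime, a pair
with gold ≥ 3.5 would have near-identical token sets and a
bag-of-words cosine of ≈ 1, and no scorer could rank it below a
contradiction pair. The generator therefore models both regimes, each
where it belongs.

The negation rule set is deliberately minimal — insert *not* at the
first infinitival site (`to interact` → `to not interact`) or after
the first auxiliary, trying modals before be/have/do forms
(`could be induced` → `could not be induced`) — matching the
restriction of such probes to simple declarative syntax; sentences
that offer no site, or are already negated, are skipped with a
warning. General negation handling is out of scope by design. The
antonym generator replaces exactly one lexicon keyword per sentence,
with a lexicon that is its own inverse.

All generators are pure functions of the configuration: fixed seed in,
byte-identical text out, on any platform, and the caller's RNG stream
is left untouched.

### What passing on fixtures does and does not show

The fixtures validate *mechanism*, not *performance on real text*: that
the metrics implement their definitions (checked against brute-force
oracles), that training recovers designed co-occurrence structure, that
the combiner is a correct OLS, and that the probe reproduces the
direction of the lexical-overlap inversion. Real biomedical sentences
have syntax, polysemy, morphology and annotation idiosyncrasies the
generator does not model; correlations measured on fixtures say nothing
quantitative about correlations on an external benchmark, which further
depend on embeddings trained on a full-scale literature corpus.

## Numerical choices and degenerate inputs

* Jaccard 0/0 → 0 with a warning; q-gram with an empty reference
  profile → 0 with a warning; cosine of a zero vector → error, mapped
  to a missing score by the evaluation layer.
* OLS via QR; coefficient recovery on noiseless data is exact to
  1e−8 and matches an explicit normal-equations solve to 1e−10.
* Correlations require n ≥ 3 and nonzero variance in both arguments;
  anything else is an error, not an `NA`.
* SVD sign indeterminacy fixed by column convention, making training
  runs bit-reproducible.
* Problem sizes used by the test and acceptance runs — 5000-line
  corpus, 600-token vocabulary, dimension 20, 100-pair benchmark —
  were chosen as the smallest scale at which the topic structure is
  reliably recovered across seeds.

## Known limitations

* The rule-based segmenter targets scientific prose; it will mis-split
  exotic abbreviation patterns. The contract accepts pre-segmented
  input for anything better.
* The built-in trainer's dense SVD is not meant for vocabularies
  beyond a few thousand types; large-scale training belongs to
  external tools, consumed via the adapters.
* The negation rule covers infinitival and auxiliary sites only;
  do-support ("binds" → "does not bind") is not generated.
* The hybrid mean assumes its inputs are on comparable scales; mixing
  in a signed cosine from centred vectors would need rescaling first.
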