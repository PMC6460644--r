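#' Sentence-pair scorer constructors
#'
#' Each constructor returns a function `(sentence1, sentence2) -> score`
#' that applies the canonical preprocessing ([preprocess_sentence()]) and
#' then one similarity measure, so scorers plug directly into
#' [evaluate_scorer()] and [contradiction_probe()]. The returned function
#' carries a `metric` attribute used for report labelling.
#'
#' * `jaccard_scorer()`: Jaccard index over the unique preprocessed
#'   tokens of the two sentences.
#' * `qgram_scorer()`: character q-gram similarity of the preprocessed
#'   sentences re-joined with single spaces (sentence 1 is the
#'   reference unless symmetrized).
#' * `embedding_scorer()`: cosine similarity of pooled word vectors (or
#'   of whole-sentence encodings); function words are kept, since
#'   embedding models are trained with them.
#' * `bow_scorer()`: cosine similarity of bag-of-words count vectors
#'   over the union vocabulary of the pair — the minimal lexical-overlap
#'   encoder used by the contradiction probe.
#'
#' @param config A [preprocess_config()].
#' @param q Gram length for `qgram_scorer()`.
#' @param symmetrize Directionality for `qgram_scorer()`; see
#'   [qgram_similarity()].
#' @param model A [word_vector_table()] or [sentence_encoder()].
#' @param pooling Pooling strategy for word tables; see [pool_vectors()].
#' @param name Metric label for `embedding_scorer()` reports.
#' @param keep_stopwords Keep function words (default `TRUE` for the
#'   embedding-style scorers, `FALSE` for string metrics)?
#' @return A scoring function of two sentences.
#' @name scorers
NULL

#' @rdname scorers
#' @export
jaccard_scorer <- function(config = preprocess_config()) {
  f <- function(sentence1, sentence2) {
    jaccard_similarity(preprocess_sentence(sentence1, config),
                       preprocess_sentence(sentence2, config))
  }
  structure(f, metric = "jaccard")
}

#' @rdname scorers
#' @export
qgram_scorer <- function(q = 3L, config = preprocess_config(),
                         symmetrize = c("none", "mean")) {
  symmetrize <- match.arg(symmetrize)
  f <- function(sentence1, sentence2) {
    s1 <- paste(preprocess_sentence(sentence1, config), collapse = " ")
    s2 <- paste(preprocess_sentence(sentence2, config), collapse = " ")
    qgram_similarity(s1, s2, q = q, symmetrize = symmetrize)
  }
  structure(f, metric = paste0("qgram", q))
}

#' @rdname scorers
#' @export
embedding_scorer <- function(model, pooling = "max",
                             config = preprocess_config(),
                             keep_stopwords = TRUE,
                             name = "embedding_cosine") {
  stopifnot(inherits(model, "word_vector_table") ||
              inherits(model, "sentence_encoder"))
  f <- function(sentence1, sentence2) {
    t1 <- preprocess_sentence(sentence1, config, keep_stopwords = keep_stopwords)
    t2 <- preprocess_sentence(sentence2, config, keep_stopwords = keep_stopwords)
    cosine_similarity(encode_sentence(model, t1, pooling),
                      encode_sentence(model, t2, pooling))
  }
  structure(f, metric = name)
}

#' @rdname scorers
#' @export
bow_scorer <- function(config = preprocess_config(), keep_stopwords = TRUE) {
  f <- function(sentence1, sentence2) {
    t1 <- preprocess_sentence(sentence1, config, keep_stopwords = keep_stopwords)
    t2 <- preprocess_sentence(sentence2, config, keep_stopwords = keep_stopwords)
    vocab <- union(t1, t2)
    if (!length(vocab)) stop("both sentences empty after preprocessing",
                             call. = FALSE)
    u <- as.numeric(table(factor(t1, levels = vocab)))
    v <- as.numeric(table(factor(t2, levels = vocab)))
    cosine_similarity(u, v)
  }
  structure(f, metric = "bow_cosine")
}

#' Score every pair of a benchmark with several metrics
#'
#' Builds the feature table consumed by the combiners: one row per
#' benchmark pair, one column per scorer. Failed scores become `NA`.
#'
#' @param scorers Named list of scoring functions.
#' @param benchmark A benchmark data frame.
#' @return Numeric matrix `nrow(benchmark) x length(scorers)` with scorer
#'   names as column names.
#' @export
score_benchmark <- function(scorers, benchmark) {
  stopifnot(is.list(scorers), length(scorers) >= 1L, is.data.frame(benchmark))
  if (is.null(names(scorers))) {
    names(scorers) <- vapply(scorers, function(s) {
      m <- attr(s, "metric")
      if (is.null(m)) "scorer" else m
    }, character(1))
  }
  out <- vapply(scorers, function(s) {
    vapply(seq_len(nrow(benchmark)), function(i) {
      tryCatch(as.numeric(s(benchmark$sentence1[i], benchmark$sentence2[i]))[1L],
               error = function(e) NA_real_)
    }, numeric(1))
  }, numeric(nrow(benchmark)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(benchmark),
                                       dimnames = list(NULL, names(scorers)))
  out
}
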