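#' Synthetic fixture configuration
#'
#' Parameters of the desk-scale generators that emulate the statistical
#' structure the pipeline assumes in real data: a topic-structured
#' sentence-per-line corpus contaminated with table-like over-long lines
#' and hyphenated compounds, and a 100-pair sentence benchmark with gold
#' scores on the 0-4 annotation scale tied to constructed token overlap.
#' All generators are pure functions of this configuration: the same
#' config yields byte-identical output on every run and platform.
#'
#' @param seed Integer master seed; each generator derives its stream
#'   from it with a small fixed offset so the outputs are decoupled.
#' @param vocab_size Number of pseudo-word tokens, split evenly across
#'   topics.
#' @param n_topics Number of latent topics; co-occurrence within a topic
#'   is what a trained embedding should recover.
#' @param n_sentences Corpus size in lines.
#' @param sentence_length Integer range (min, max) of tokens per corpus
#'   sentence.
#' @param benchmark_size Number of benchmark sentence pairs.
#' @param overlap_noise Standard deviation of the Gaussian annotation
#'   noise added to `4 * overlap` when generating gold scores.
#' @param fraction_long_lines Fraction of corpus lines rendered as
#'   over-long pseudo-table lines (always at least 200 characters, so
#'   the long-line filter removes exactly this many).
#' @param fraction_hyphenated Fraction of prose lines containing one
#'   hyphenated compound.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, vocab_size = 600L, n_topics = 6L,
                           n_sentences = 5000L, sentence_length = c(6L, 14L),
                           benchmark_size = 100L, overlap_noise = 0.25,
                           fraction_long_lines = 0.02,
                           fraction_hyphenated = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    vocab_size = as.integer(vocab_size),
    n_topics = as.integer(n_topics),
    n_sentences = as.integer(n_sentences),
    sentence_length = as.integer(sentence_length),
    benchmark_size = as.integer(benchmark_size),
    overlap_noise = as.numeric(overlap_noise),
    fraction_long_lines = as.numeric(fraction_long_lines),
    fraction_hyphenated = as.numeric(fraction_hyphenated)
  )
  with(cfg, {
    if (any(c(vocab_size, n_topics, n_sentences, benchmark_size) <= 0L)) {
      stop("all counts must be positive", call. = FALSE)
    }
    if (length(sentence_length) != 2L || sentence_length[1L] < 1L ||
        sentence_length[2L] < sentence_length[1L]) {
      stop("'sentence_length' must be an increasing positive range", call. = FALSE)
    }
    if (overlap_noise < 0) stop("'overlap_noise' must be >= 0", call. = FALSE)
    if (fraction_long_lines < 0 || fraction_long_lines > 1 ||
        fraction_hyphenated < 0 || fraction_hyphenated > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
    if (vocab_size %/% n_topics < 30L) {
      stop("vocabulary too small for ", n_topics,
           " topics: need at least 30 tokens per topic", call. = FALSE)
    }
  })
  structure(cfg, class = "fixture_config")
}

#' Topic vocabularies of the synthetic generator
#'
#' Deterministic pseudo-word vocabulary (pronounceable consonant-vowel
#' tokens, so they resemble rare domain terms rather than English words),
#' split evenly across topics.
#'
#' @param config A [fixture_config()].
#' @return A list with one character vector of tokens per topic.
#' @export
fixture_vocabulary <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  syllables <- as.vector(outer(consonants, vowels, paste0))
  pool <- as.vector(outer(syllables, syllables, paste0))   # 4900 distinct words
  pool <- setdiff(pool, default_stopwords())
  if (config$vocab_size > length(pool)) {
    stop("'vocab_size' exceeds the generator's word pool (",
         length(pool), ")", call. = FALSE)
  }
  words <- with_seed(config$seed + 101L, sample(pool, config$vocab_size))
  per_topic <- config$vocab_size %/% config$n_topics
  lapply(seq_len(config$n_topics), function(t) {
    words[seq.int((t - 1L) * per_topic + 1L, t * per_topic)]
  })
}

# One pseudo-table line of at least 210 characters (numeric columns).
make_long_line <- function() {
  vals <- sprintf("%07.2f", stats::runif(35, 0, 9999))
  line <- paste(vals, collapse = " ")
  while (nchar(line) < 210L) line <- paste(line, paste(vals, collapse = " "))
  substring(line, 1L, 260L)
}

#' Generate a synthetic training corpus
#'
#' Sentence-per-line corpus with topic structure: each prose line draws
#' all its tokens from a single topic vocabulary, so co-occurrence
#' encodes topic membership. A configured fraction of lines are over-long
#' pseudo-table lines (at least 200 characters, removed exactly by the
#' long-line filter), and a configured fraction of prose lines contain
#' one hyphenated compound. Deterministic per configuration.
#'
#' @param config A [fixture_config()].
#' @param output Optional path to write the corpus (UTF-8, one line per
#'   sentence).
#' @return Character vector of corpus lines with attribute `topic`
#'   (integer topic per line, `NA` for pseudo-table lines).
#' @export
generate_corpus <- function(config = fixture_config(), output = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  vocab <- fixture_vocabulary(config)
  n <- config$n_sentences
  n_long <- round(config$fraction_long_lines * n)

  res <- with_seed(config$seed, {
    long_at <- if (n_long > 0L) sort(sample.int(n, n_long)) else integer(0)
    topic <- rep(NA_integer_, n)
    lines <- character(n)
    prose <- setdiff(seq_len(n), long_at)
    n_hyph <- round(config$fraction_hyphenated * length(prose))
    hyph_at <- if (n_hyph > 0L) sample(prose, n_hyph) else integer(0)
    for (i in prose) {
      t <- sample.int(config$n_topics, 1L)
      topic[i] <- t
      len <- sample(seq.int(config$sentence_length[1L],
                            config$sentence_length[2L]), 1L)
      toks <- sample(vocab[[t]], len, replace = TRUE)
      if (i %in% hyph_at && len >= 2L) {
        toks <- c(paste(toks[1L], toks[2L], sep = "-"), toks[-(1:2)])
      }
      lines[i] <- paste(toks, collapse = " ")
    }
    for (i in long_at) lines[i] <- make_long_line()
    list(lines = lines, topic = topic)
  })

  out <- res$lines
  attr(out, "topic") <- res$topic
  if (!is.null(output)) {
    con <- file(output, open = "wb")
    on.exit(close(con))
    writeLines(as.character(out), con, useBytes = TRUE)
  }
  out
}

#' Generate a synthetic sentence-pair benchmark
#'
#' Pairs with controlled unique-token overlap spanning `[0, 1]`: sentence
#' 1 draws its tokens from one topic; sentence 2 shares a set fraction of
#' them and fills the rest from a different topic, so lexical overlap and
#' topical relatedness move together, as they do in citation-derived
#' benchmark pairs. The gold score is `4 * overlap + N(0, sigma)` clipped
#' to `[0, 4]`, with `sigma = config$overlap_noise` emulating annotator
#' disagreement. At `sigma = 0` the gold score is exactly four times the
#' realized unique-token Jaccard of the preprocessed sentences.
#'
#' @param config A [fixture_config()].
#' @param tokens_per_sentence Unique tokens per sentence.
#' @return A benchmark data frame (`pair_id`, `sentence1`, `sentence2`,
#'   `gold`, `subset = "main"`) with attribute `overlap` holding each
#'   pair's constructed unique-token overlap.
#' @export
generate_benchmark <- function(config = fixture_config(),
                               tokens_per_sentence = 8L) {
  stopifnot(inherits(config, "fixture_config"))
  u <- as.integer(tokens_per_sentence)
  if (u < 2L) stop("'tokens_per_sentence' must be >= 2", call. = FALSE)
  if (config$n_topics < 2L) {
    stop("benchmark generation needs at least 2 topics", call. = FALSE)
  }
  vocab <- fixture_vocabulary(config)
  n <- config$benchmark_size
  shared_counts <- round(u * (seq_len(n) - 1) / max(1L, n - 1L))

  res <- with_seed(config$seed + 202L, {
    shared_counts <- sample(shared_counts)   # decouple overlap from pair order
    s1 <- character(n); s2 <- character(n)
    overlap <- numeric(n); gold <- numeric(n)
    for (i in seq_len(n)) {
      s <- shared_counts[i]
      tA <- sample.int(config$n_topics, 1L)
      tB <- sample(setdiff(seq_len(config$n_topics), tA), 1L)
      tokens1 <- sample(vocab[[tA]], u)
      shared <- tokens1[seq_len(s)]
      fill <- if (u - s > 0L) sample(vocab[[tB]], u - s) else character(0)
      tokens2 <- sample(c(shared, fill))
      overlap[i] <- s / (2L * u - s)
      g <- 4 * overlap[i] + stats::rnorm(1L, 0, config$overlap_noise)
      gold[i] <- min(4, max(0, g))
      s1[i] <- paste0(paste(tokens1, collapse = " "), ".")
      s2[i] <- paste0(paste(tokens2, collapse = " "), ".")
    }
    list(s1 = s1, s2 = s2, overlap = overlap, gold = gold)
  })

  out <- data.frame(
    pair_id = sprintf("p%03d", seq_len(n)),
    sentence1 = res$s1,
    sentence2 = res$s2,
    gold = res$gold,
    subset = "main",
    stringsAsFactors = FALSE
  )
  attr(out, "overlap") <- res$overlap
  out
}

#' Generate paraphrase-style highly similar pairs
#'
#' The reference subset for the contradiction probe: pairs an expert
#' would rate as highly similar (gold drawn from `[3.5, 4]`) although the
#' two sentences share only part of their wording, as real paraphrases
#' do. Both sentences draw from the same topic; a moderate fraction of
#' tokens is shared (unique-token Jaccard about 0.3-0.6), so
#' lexical-overlap scorers rate these pairs well below near-identical
#' contradiction pairs.
#'
#' @param config A [fixture_config()].
#' @param n Number of pairs.
#' @param tokens_per_sentence Unique tokens per sentence.
#' @return A benchmark data frame with `subset = "high_similarity"`.
#' @export
generate_similar_pairs <- function(config = fixture_config(), n = 11L,
                                   tokens_per_sentence = 10L) {
  stopifnot(inherits(config, "fixture_config"))
  u <- as.integer(tokens_per_sentence)
  vocab <- fixture_vocabulary(config)
  res <- with_seed(config$seed + 303L, {
    s1 <- character(n); s2 <- character(n); gold <- numeric(n)
    for (i in seq_len(n)) {
      t <- sample.int(config$n_topics, 1L)
      s <- sample(seq.int(ceiling(u * 0.4), ceiling(u * 0.6)), 1L)
      toks <- sample(vocab[[t]], 2L * u - s)
      tokens1 <- toks[seq_len(u)]
      tokens2 <- sample(c(tokens1[seq_len(s)], toks[seq.int(u + 1L, 2L * u - s)]))
      gold[i] <- stats::runif(1L, 3.5, 4)
      s1[i] <- paste0(paste(tokens1, collapse = " "), ".")
      s2[i] <- paste0(paste(tokens2, collapse = " "), ".")
    }
    list(s1 = s1, s2 = s2, gold = gold)
  })
  data.frame(
    pair_id = sprintf("h%03d", seq_len(n)),
    sentence1 = res$s1,
    sentence2 = res$s2,
    gold = res$gold,
    subset = "high_similarity",
    stringsAsFactors = FALSE
  )
}

#' Simple declarative source sentences for the contradiction generators
#'
#' Template-based sentences with a simple syntactic structure — one
#' clause, one negation site or one antonym keyword — mirroring how
#' contradiction-probe candidates are selected in practice. The
#' `"negation"` style yields sentences with an infinitival or auxiliary
#' negation site; the `"antonym"` style yields sentences containing one
#' keyword of [antonym_lexicon()].
#'
#' @param config A [fixture_config()].
#' @param n Number of sentences.
#' @param style `"negation"` or `"antonym"`.
#' @return Character vector of sentences.
#' @export
generate_statement_sentences <- function(config = fixture_config(), n = 13L,
                                         style = c("negation", "antonym")) {
  style <- match.arg(style)
  stopifnot(inherits(config, "fixture_config"))
  vocab <- fixture_vocabulary(config)
  templates <- if (style == "negation") {
    c("%s was reported to interact with %s.",
      "%s was shown to regulate %s.",
      "%s could be induced via modulating %s.",
      "%s appears to modulate %s in tumour cells.",
      "%s has been observed to bind %s.")
  } else {
    c("overexpression of oncogenic %s induces premature %s senescence in primary tumour cells.",
      "%s strongly promotes %s expression during early myeloid differentiation in culture.",
      "%s depletion led to impaired %s hematopoietic differentiation and preferential myeloid commitment.",
      "binding of %s activates downstream %s signaling in resting immune cells.",
      "sustained expression of %s increases circulating %s levels in treated animals.")
  }
  with_seed(config$seed + 404L + (style == "antonym"), {
    vapply(seq_len(n), function(i) {
      t <- sample.int(config$n_topics, 1L)
      ab <- sample(vocab[[t]], 2L)
      sprintf(templates[(i - 1L) %% length(templates) + 1L], ab[1L], ab[2L])
    }, character(1))
  })
}

#' Default antonym lexicon
#'
#' Keyword-to-antonym map used to flip a sentence's meaning by replacing
#' exactly one word (for example `induces` to `inhibits`, `impaired` to
#' `enhanced`). The map is its own inverse and no token maps to itself.
#'
#' @return Named character vector: `names()` are keywords, values their
#'   antonyms.
#' @export
antonym_lexicon <- function() {
  pairs <- c(
    induces = "inhibits", impaired = "enhanced", increases = "decreases",
    promotes = "suppresses", activates = "represses",
    upregulated = "downregulated"
  )
  c(pairs, stats::setNames(names(pairs), unname(pairs)))
}

# tried in order: modal auxiliaries bind the negation site more tightly
# than be/have/do forms ("could be induced" -> "could not be induced")
negation_aux_tiers <- list(
  c("could", "can", "may", "might", "must", "will", "would", "shall", "should"),
  c("was", "were", "is", "are", "am", "be", "been"),
  c("has", "have", "had", "does", "do", "did")
)

#' Generate negation contradiction pairs
#'
#' For each source sentence, inserts `not` at its negation site: before
#' the verb of the first infinitival `to <verb>` group, or after the
#' first auxiliary when no infinitive is present
#' (`"could be induced"` to `"could not be induced"`). Sentences that are
#' already negated or offer no site are skipped with a warning. Because
#' only one token is inserted, each pair shares almost all tokens with
#' its original (unique-token Jaccard at least 0.8 for the simple
#' sentences this rule set targets).
#'
#' @param sentences Character vector of simple declarative sentences.
#' @return A benchmark data frame (`subset = "negation"`, gold absent)
#'   with one row per successfully negated sentence.
#' @examples
#' generate_negation_pairs("Rip1 was reported to interact with rip3.")
#' @export
generate_negation_pairs <- function(sentences) {
  stopifnot(is.character(sentences))
  negated <- character(0)
  original <- character(0)
  for (s in sentences) {
    if (grepl("\\bnot\\b", s, ignore.case = TRUE)) {
      warning("skipping already-negated sentence: ", s, call. = FALSE)
      next
    }
    if (grepl("\\bto ([[:alpha:]]+)", s)) {
      neg <- sub("\\bto ([[:alpha:]]+)", "to not \\1", s)
    } else {
      neg <- NULL
      for (tier in negation_aux_tiers) {
        aux_pattern <- paste0("\\b(", paste(tier, collapse = "|"), ")\\b")
        if (grepl(aux_pattern, s, ignore.case = TRUE)) {
          neg <- sub(paste0("(", aux_pattern, ")"), "\\1 not", s,
                     ignore.case = TRUE)
          break
        }
      }
      if (is.null(neg)) {
        warning("no negation site found, skipping: ", s, call. = FALSE)
        next
      }
    }
    original <- c(original, s)
    negated <- c(negated, neg)
  }
  if (!length(original)) {
    return(data.frame(pair_id = character(0), sentence1 = character(0),
                      sentence2 = character(0), gold = numeric(0),
                      subset = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    pair_id = sprintf("n%03d", seq_along(original)),
    sentence1 = original,
    sentence2 = negated,
    gold = NA_real_,
    subset = "negation",
    stringsAsFactors = FALSE
  )
}

#' Generate antonym contradiction pairs
#'
#' Replaces exactly one lexicon keyword per sentence with its antonym,
#' leaving every other token identical, so the pair's meaning is flipped
#' while its wording barely changes. Sentences containing no keyword are
#' skipped with a warning.
#'
#' @param sentences Character vector of sentences each containing at
#'   least one lexicon keyword.
#' @param lexicon Named character vector mapping keywords to antonyms;
#'   see [antonym_lexicon()].
#' @return A benchmark data frame (`subset = "antonym"`, gold absent).
#' @examples
#' generate_antonym_pairs("oncogenic ras induces premature senescence.")
#' @export
generate_antonym_pairs <- function(sentences, lexicon = antonym_lexicon()) {
  stopifnot(is.character(sentences), is.character(lexicon),
            !is.null(names(lexicon)))
  if (any(names(lexicon) == unname(lexicon))) {
    stop("lexicon must not map a token to itself", call. = FALSE)
  }
  flipped <- character(0)
  original <- character(0)
  for (s in sentences) {
    hit <- NULL
    for (kw in names(lexicon)) {
      if (grepl(paste0("\\b", kw, "\\b"), s)) { hit <- kw; break }
    }
    if (is.null(hit)) {
      warning("no lexicon keyword found, skipping: ", s, call. = FALSE)
      next
    }
    original <- c(original, s)
    flipped <- c(flipped, sub(paste0("\\b", hit, "\\b"), lexicon[[hit]], s))
  }
  if (!length(original)) {
    return(data.frame(pair_id = character(0), sentence1 = character(0),
                      sentence2 = character(0), gold = numeric(0),
                      subset = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    pair_id = sprintf("a%03d", seq_along(original)),
    sentence1 = original,
    sentence2 = flipped,
    gold = NA_real_,
    subset = "antonym",
    stringsAsFactors = FALSE
  )
}
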