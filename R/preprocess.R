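#' Preprocessing configuration
#'
#' Bundles the corpus-preparation heuristics applied before any similarity
#' scoring: the long-line filter threshold, hyphen-compound splitting, case
#' folding, and the stopword and punctuation lists used by the string-based
#' metrics.
#'
#' @param max_line_chars Lines with this many characters or more are removed
#'   by [filter_long_lines()]. The filter is strict (`<`), so the default of
#'   200 keeps lines of up to 199 characters. Long lines in full-text corpora
#'   are typically table content rather than prose.
#' @param split_hyphens Split compound words joined by hyphens
#'   (`"anti-HER2"` becomes `"anti HER2"`)? Applies only between
#'   alphanumeric neighbours; leading and trailing hyphens are stripped.
#' @param lowercase Case-fold all text before tokenization?
#' @param stopwords Character vector of stopwords removed (case-insensitively)
#'   by [remove_stopwords()]. Defaults to the list shipped with the package
#'   (see [default_stopwords()]). The choice of list measurably shifts
#'   string-metric scores, so it is data, not code.
#' @param punctuation Character vector of punctuation tokens removed by
#'   [remove_stopwords()]. The default covers full stop, comma, colon,
#'   semicolon, question mark, exclamation mark, slash and dash.
#'
#' @return An object of class `preprocess_config` (a named list).
#' @examples
#' cfg <- preprocess_config()
#' cfg$max_line_chars
#' @export
preprocess_config <- function(max_line_chars = 200L,
                              split_hyphens = TRUE,
                              lowercase = TRUE,
                              stopwords = default_stopwords(),
                              punctuation = c(".", ",", ":", ";", "?", "!", "/", "-")) {
  max_line_chars <- as.integer(max_line_chars)
  if (is.na(max_line_chars) || max_line_chars <= 0L) {
    stop("'max_line_chars' must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      max_line_chars = max_line_chars,
      split_hyphens = isTRUE(split_hyphens),
      lowercase = isTRUE(lowercase),
      stopwords = tolower(as.character(stopwords)),
      punctuation = as.character(punctuation)
    ),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("Preprocessing configuration\n")
  cat("  max_line_chars:", x$max_line_chars, "(strict <)\n")
  cat("  split_hyphens: ", x$split_hyphens, "\n")
  cat("  lowercase:     ", x$lowercase, "\n")
  cat("  stopwords:     ", length(x$stopwords), "entries\n")
  cat("  punctuation:   ", paste(x$punctuation, collapse = " "), "\n")
  invisible(x)
}

#' Default English stopword list
#'
#' Returns the packaged list of common English stopwords (about 150 entries)
#' removed before string-based similarity scoring.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "sentsim")
  if (!nzchar(path)) stop("packaged stopword list not found", call. = FALSE)
  readLines(path, encoding = "UTF-8")
}

#' Abbreviations protected from sentence splitting
#'
#' The rule-based segmenter does not split after these tokens even when a
#' period is followed by whitespace and a capital letter. Single-letter
#' tokens (author initials) are always protected.
#'
#' @return Character vector of lowercase abbreviation stems (without the
#'   trailing period).
#' @export
default_abbreviations <- function() {
  c("e.g", "i.e", "fig", "figs", "eq", "eqs", "ref", "refs", "tab",
    "vs", "cf", "ca", "et", "al", "dr", "prof", "inc", "resp",
    "approx", "spp", "subsp", "st")
}

#' Split a document into sentences
#'
#' Deterministic rule-based sentence boundary detection: a boundary is a run
#' of terminal punctuation (`.`, `?`, `!`) followed by whitespace and an
#' upper-case letter, digit or opening quote/parenthesis, unless the
#' preceding token is a protected abbreviation or a single letter. The
#' returned sentences partition the document, so concatenating them recovers
#' its non-whitespace content. An external segmenter can be substituted
#' anywhere a sentence vector is accepted.
#'
#' @param document A length-one character string.
#' @param abbreviations Lowercase abbreviation stems that block a boundary;
#'   see [default_abbreviations()].
#' @return Character vector of sentences (possibly empty for blank input).
#' @examples
#' segment_sentences("Rip1 was reported to interact with rip3. Moreover, other reports exist.")
#' @export
segment_sentences <- function(document, abbreviations = default_abbreviations()) {
  if (!is.character(document) || length(document) != 1L) {
    stop("'document' must be a single character string", call. = FALSE)
  }
  doc <- gsub("[\r\n]+", " ", document)
  if (!nzchar(trimws(doc))) return(character(0))

  cand <- gregexpr("[.?!]", doc)[[1L]]
  ends <- integer(0)
  if (cand[1L] != -1L) {
    for (pos in cand) {
      rest <- substring(doc, pos + 1L)
      if (!grepl("^[[:space:]]", rest)) next
      nxt <- sub("^[[:space:]]+", "", rest)
      if (nzchar(nxt) && !grepl("^[A-Z0-9(\"']", nxt)) next
      before <- substring(doc, 1L, pos - 1L)
      word <- tolower(sub("^.*[[:space:]]", "", before))
      word <- sub("^[^[:alnum:]]+", "", word)
      if (word %in% abbreviations) next
      if (grepl("^[[:alnum:]]$", word)) next   # author initials, list markers
      ends <- c(ends, pos)
    }
  }
  ends <- sort(unique(c(ends, nchar(doc))))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  sentences <- trimws(substring(doc, starts, ends))
  sentences[nzchar(sentences)]
}

#' Tokenize one sentence
#'
#' Splits on whitespace after isolating the punctuation marks in the
#' configuration as standalone tokens. Hyphens joining two alphanumeric
#' characters are kept inside the token (compound splitting is a separate,
#' configurable step; see [split_hyphens()]); other hyphens become
#' standalone tokens.
#'
#' @param text A length-one character string.
#' @param config A [preprocess_config()].
#' @return Character vector of tokens.
#' @examples
#' tokenize_sentence("The up-regulation of miR-146a was detected.")
#' @export
tokenize_sentence <- function(text, config = preprocess_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- if (config$lowercase) tolower(text) else text
  marks <- setdiff(config$punctuation, "-")
  if (length(marks)) {
    x <- gsub(paste0("([", gsub("([][\\^-])", "\\\\\\1", paste(marks, collapse = "")), "])"),
              " \\1 ", x)
  }
  if ("-" %in% config$punctuation) {
    x <- gsub("(?<![[:alnum:]])-|-(?![[:alnum:]])", " - ", x, perl = TRUE)
  }
  x <- trimws(gsub("[[:space:]]+", " ", x))
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

#' Segment a document and tokenize each sentence
#'
#' Applies [segment_sentences()] then [tokenize_sentence()]; the unit of all
#' downstream scoring. Each element keeps the raw sentence string it came
#' from.
#'
#' @inheritParams tokenize_sentence
#' @param document A length-one character string; an empty document yields
#'   an empty list.
#' @return A list of `tokenized_sentence` objects, each with elements
#'   `raw` (the original sentence string) and `tokens`.
#' @export
segment_and_tokenize <- function(document, config = preprocess_config()) {
  sentences <- segment_sentences(document)
  lapply(sentences, function(s) {
    structure(list(raw = s, tokens = tokenize_sentence(s, config)),
              class = "tokenized_sentence")
  })
}

#' @export
print.tokenized_sentence <- function(x, ...) {
  cat("<tokenized sentence> ", x$raw, "\n  tokens: ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Split hyphenated compound words
#'
#' Replaces hyphens joining two alphanumeric characters with a space
#' (`"anti-HER2"` to `"anti HER2"`) and strips leading/trailing hyphens from
#' tokens. Every non-hyphen, non-space character is preserved; token order
#' is unchanged.
#'
#' @param x Character vector of lines or tokens.
#' @return Character vector of the same length.
#' @examples
#' split_hyphens("rnai-mediated tet2 knock-down")
#' @export
split_hyphens <- function(x) {
  stopifnot(is.character(x))
  x <- gsub("(?<=[[:alnum:]])-+(?=[[:alnum:]])", " ", x, perl = TRUE)
  x <- gsub("(^|[[:space:]])-+", "\\1", x)
  gsub("-+([[:space:]]|$)", "\\1", x)
}

#' Remove stopwords and punctuation tokens
#'
#' Drops every token that matches the configured stopword list
#' (case-insensitively) or the configured punctuation marks; the relative
#' order of the remaining tokens is preserved. The result may be empty and
#' callers must handle an empty token set.
#'
#' @param tokens Character vector of tokens.
#' @param config A [preprocess_config()].
#' @return Character vector (a subsequence of `tokens`).
#' @examples
#' remove_stopwords(c("the", "expression", "of", "mir146a"))
#' @export
remove_stopwords <- function(tokens, config = preprocess_config()) {
  stopifnot(is.character(tokens))
  if (!length(tokens)) return(character(0))
  keep <- !(tolower(tokens) %in% config$stopwords) & !(tokens %in% config$punctuation)
  tokens[keep]
}

#' Filter excessively long corpus lines
#'
#' Keeps only lines strictly shorter than `config$max_line_chars`
#' characters. In full-text corpora the over-long lines are mostly tables
#' and other non-prose content that degrade embedding training. Idempotent;
#' order preserved.
#'
#' @param lines Character vector of corpus lines.
#' @param config A [preprocess_config()].
#' @return The subsequence of `lines` with `nchar(line) < max_line_chars`.
#' @export
filter_long_lines <- function(lines, config = preprocess_config()) {
  stopifnot(is.character(lines))
  lines[nchar(lines) < config$max_line_chars]
}

#' Corpus summary statistics
#'
#' @param lines Character vector of corpus lines (tokens separated by
#'   single spaces).
#' @return A list of class `corpus_stats`: `n_lines`, `n_tokens`,
#'   `n_unique_tokens`, `mean_line_length` and `max_line_length` (both in
#'   characters).
#' @export
corpus_stats <- function(lines) {
  stopifnot(is.character(lines))
  tokens <- unlist(strsplit(lines, "[[:space:]]+"), use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  lens <- nchar(lines)
  structure(
    list(
      n_lines = length(lines),
      n_tokens = length(tokens),
      n_unique_tokens = length(unique(tokens)),
      mean_line_length = if (length(lines)) mean(lens) else 0,
      max_line_length = if (length(lines)) max(lens) else 0
    ),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("Corpus statistics\n")
  cat("  lines:           ", x$n_lines, "\n")
  cat("  tokens:          ", x$n_tokens, "\n")
  cat("  unique tokens:   ", x$n_unique_tokens, "\n")
  cat(sprintf("  mean line length: %.1f chars\n", x$mean_line_length))
  cat("  max line length: ", x$max_line_length, "chars\n")
  invisible(x)
}

#' Build a sentence-per-line training corpus
#'
#' Runs the full corpus-preparation pipeline over a set of documents:
#' sentence segmentation, tokenization, optional hyphen-compound splitting,
#' optional stopword/punctuation removal, then the long-line filter. Each
#' output line is one processed sentence with tokens joined by single
#' spaces. Deterministic for fixed input and configuration.
#'
#' Stopword removal defaults to off here: the embedding-training corpus
#' keeps function words, which carry context for the training objective;
#' stopwords are removed later, inside the string-based scorers.
#'
#' @param documents Character vector: either document texts or paths to
#'   UTF-8 `.txt` files (paths are detected per element via `file.exists`).
#' @param config A [preprocess_config()].
#' @param remove_stopwords Also drop stopword and punctuation tokens from
#'   every line?
#' @param output Optional path; when given, lines are written there
#'   (UTF-8, one sentence per line).
#' @return A list with `lines` (character vector) and `stats`
#'   (a [corpus_stats()] object computed over the post-processed corpus).
#' @export
build_corpus <- function(documents, config = preprocess_config(),
                         remove_stopwords = FALSE, output = NULL) {
  if (!is.character(documents) || length(documents) == 0L) {
    stop("'documents' must be a non-empty character vector", call. = FALSE)
  }
  texts <- vapply(documents, function(d) {
    looks_like_path <- nchar(d) < 1000L &&
      (grepl("\\.txt$", d, ignore.case = TRUE) || file.exists(d))
    if (looks_like_path) {
      if (!file.exists(d)) {
        stop("cannot read document: ", d, call. = FALSE)
      }
      paste(readLines(d, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    } else {
      d
    }
  }, character(1), USE.NAMES = FALSE)

  lines <- unlist(lapply(texts, function(txt) {
    sentences <- segment_sentences(txt)
    vapply(sentences, function(s) {
      if (config$split_hyphens) s <- split_hyphens(s)
      tokens <- tokenize_sentence(s, config)
      if (remove_stopwords) tokens <- remove_stopwords(tokens, config)
      paste(tokens, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- filter_long_lines(lines, config)

  if (!is.null(output)) {
    con <- file(output, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  list(lines = lines, stats = corpus_stats(lines))
}

#' Full per-sentence preprocessing for string-based scoring
#'
#' The canonical path from a raw sentence to the token sequence scored by
#' the string metrics: case folding, hyphen splitting, tokenization, then
#' stopword and punctuation removal.
#'
#' @param text A length-one character string.
#' @param config A [preprocess_config()].
#' @param keep_stopwords Skip the stopword/punctuation removal step (used
#'   by embedding-style scorers, which keep function words)? Punctuation
#'   tokens are still dropped.
#' @return Character vector of tokens (possibly empty).
#' @export
preprocess_sentence <- function(text, config = preprocess_config(),
                                keep_stopwords = FALSE) {
  x <- text
  if (config$split_hyphens) x <- split_hyphens(x)
  tokens <- tokenize_sentence(x, config)
  if (keep_stopwords) {
    tokens[!(tokens %in% config$punctuation)]
  } else {
    remove_stopwords(tokens, config)
  }
}
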