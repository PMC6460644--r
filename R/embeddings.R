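#' Word-vector table
#'
#' Container for per-token embeddings: a numeric matrix with one row per
#' vocabulary token. Lookups of out-of-vocabulary tokens are always
#' reported to the caller, never silently zero-filled.
#'
#' @param vectors Numeric matrix, one row per token, with unique rownames.
#' @param provenance Optional list describing how the vectors were
#'   produced (algorithm, configuration, seed).
#' @return An object of class `word_vector_table`.
#' @export
word_vector_table <- function(vectors, provenance = list()) {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("'vectors' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors))) {
    stop("'vectors' must have unique rownames (the vocabulary)", call. = FALSE)
  }
  if (ncol(vectors) < 1L) stop("embedding dimension must be positive", call. = FALSE)
  structure(
    list(vectors = vectors, dimension = ncol(vectors), provenance = provenance),
    class = "word_vector_table"
  )
}

#' @export
print.word_vector_table <- function(x, ...) {
  cat("Word-vector table:", nrow(x$vectors), "tokens x", x$dimension, "dimensions\n")
  if (!is.null(x$provenance$algorithm)) {
    cat("  algorithm:", x$provenance$algorithm, "\n")
  }
  if (!is.null(x$provenance$seed)) cat("  seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' @rdname word_vector_table
#' @param table A `word_vector_table`.
#' @export
vocabulary <- function(table) {
  stopifnot(inherits(table, "word_vector_table"))
  rownames(table$vectors)
}

#' Pool a set of word vectors into one sentence vector
#'
#' Element-wise reduction across vectors: `max`, `min`, `sum` or `mean`
#' (exposed also as `"average"`). Pooling is permutation-invariant over
#' the vector list, and mean pooling equals sum pooling scaled by `1/n`,
#' so cosine scores are identical under the two.
#'
#' @param vectors A numeric matrix (one vector per row) or a list of
#'   equal-length numeric vectors; at least one vector is required.
#' @param strategy One of `"max"`, `"min"`, `"sum"`, `"mean"`/`"average"`.
#' @return Numeric vector of the common length.
#' @examples
#' pool_vectors(rbind(c(1, 0), c(0, 1)), "max")
#' @export
pool_vectors <- function(vectors, strategy = c("max", "min", "sum", "mean", "average")) {
  strategy <- match.arg(strategy)
  if (strategy == "average") strategy <- "mean"
  if (is.list(vectors)) {
    if (!length(vectors)) stop("no in-vocabulary tokens: empty vector list", call. = FALSE)
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L) {
      stop("all vectors must have the same length (got lengths ",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || !is.numeric(vectors) || nrow(vectors) == 0L) {
    stop("no in-vocabulary tokens: empty vector list", call. = FALSE)
  }
  switch(strategy,
    max  = apply(vectors, 2L, max),
    min  = apply(vectors, 2L, min),
    sum  = colSums(vectors),
    mean = colMeans(vectors)
  )
}

#' Cosine similarity of two vectors
#'
#' The cosine of the angle between `u` and `v`:
#' \eqn{\cos\theta = (u \cdot v) / (\lVert u\rVert \, \lVert v\rVert)}.
#' Symmetric and invariant to positive rescaling of either argument.
#'
#' @param u,v Numeric vectors of equal length; neither may be all zero
#'   (the cosine is undefined there and an error is raised; report layers
#'   map it to a flagged missing score).
#' @return A score in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v)) stop("inputs must be numeric", call. = FALSE)
  if (length(u) != length(v)) {
    stop("vectors must have equal length (", length(u), " vs ", length(v), ")",
         call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined cosine: zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Embedding training configuration
#'
#' Configuration surface for [train_word_table()]. The built-in trainer is
#' a count-based model — positive pointwise mutual information (PPMI)
#' weighting of a symmetric token co-occurrence matrix followed by a
#' truncated SVD — which is fully deterministic. Externally trained
#' predictive models (skip-gram, CBOW, sentence encoders) enter through
#' [read_word_vectors()] and [sentence_encoder()].
#'
#' @param algorithm Currently `"ppmi-svd"`.
#' @param dimension Embedding dimension (positive integer).
#' @param window Symmetric co-occurrence window in tokens.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (tokens below the threshold are dropped entirely).
#' @param seed Integer recorded in the table's provenance; the trainer is
#'   deterministic, so the seed only documents the run.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(algorithm = "ppmi-svd", dimension = 100L,
                             window = 5L, min_count = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm, "ppmi-svd")
  dimension <- as.integer(dimension)
  window <- as.integer(window)
  min_count <- as.integer(min_count)
  if (dimension < 1L) stop("'dimension' must be positive", call. = FALSE)
  if (window < 1L) stop("'window' must be positive", call. = FALSE)
  if (min_count < 1L) stop("'min_count' must be >= 1", call. = FALSE)
  structure(
    list(algorithm = algorithm, dimension = dimension, window = window,
         min_count = min_count, seed = as.integer(seed)),
    class = "embedding_config"
  )
}

#' Train a word-vector table on a sentence-per-line corpus
#'
#' Builds a symmetric token co-occurrence matrix over a sliding window,
#' re-weights it with positive pointwise mutual information, and factors
#' it with a truncated SVD; row `i` of \eqn{U_d \sqrt{\Sigma_d}} is the
#' embedding of token `i`. The vocabulary covers exactly the tokens whose
#' corpus frequency reaches `min_count`. The procedure is deterministic:
#' two runs on the same corpus and configuration produce identical tables
#' (singular-vector signs are fixed by convention).
#'
#' @param corpus Path to a sentence-per-line text file, or a character
#'   vector of corpus lines (tokens separated by whitespace).
#' @param config An [embedding_config()].
#' @return A [word_vector_table()] whose provenance records the
#'   configuration, seed and corpus size.
#' @export
train_word_table <- function(corpus, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  lines <- if (length(corpus) == 1L && file.exists(corpus)) {
    readLines(corpus, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(corpus)
  }
  lines <- lines[nzchar(lines)]
  token_lines <- strsplit(tolower(lines), "[[:space:]]+")

  tokens <- unlist(token_lines, use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  counts <- table(tokens)
  vocab <- sort(names(counts)[counts >= config$min_count])
  if (length(vocab) < 2L) {
    stop("corpus too small: effective vocabulary size is ", length(vocab),
         " at min_count = ", config$min_count, call. = FALSE)
  }

  # flat token stream with line ids so windows never cross sentences
  ids <- match(tokens, vocab)                       # NA for sub-threshold tokens
  line_id <- rep.int(seq_along(token_lines), lengths(token_lines))
  keep <- !is.na(ids)
  ids <- ids[keep]
  line_id <- line_id[keep]

  nv <- length(vocab)
  cooc <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nv, nv))
  n <- length(ids)
  for (d in seq_len(config$window)) {
    if (n <= d) break
    i <- ids[seq_len(n - d)]
    j <- ids[seq_len(n - d) + d]
    same <- line_id[seq_len(n - d)] == line_id[seq_len(n - d) + d]
    if (!any(same)) next
    inc <- Matrix::sparseMatrix(i = i[same], j = j[same], x = 1, dims = c(nv, nv))
    cooc <- cooc + inc + Matrix::t(inc)
  }

  total <- sum(cooc)
  if (total == 0) {
    stop("corpus too small: no co-occurrences within the window", call. = FALSE)
  }
  row_marg <- Matrix::rowSums(cooc)
  dense <- as.matrix(cooc)
  # PPMI_ij = max(0, log(P(i,j) / (P(i) P(j)))) with P from co-occurrence counts
  ratio <- dense * total / outer(row_marg, row_marg)
  ppmi <- ifelse(is.finite(ratio) & ratio > 1, log(ratio), 0)

  k <- min(config$dimension, nv)
  dec <- svd(ppmi, nu = k, nv = 0)
  emb <- dec$u %*% diag(sqrt(dec$d[seq_len(k)]), nrow = k)
  # fix sign indeterminacy: largest-magnitude loading of each column positive
  for (col in seq_len(k)) {
    peak <- which.max(abs(emb[, col]))
    if (emb[peak, col] < 0) emb[, col] <- -emb[, col]
  }
  if (k < config$dimension) {
    emb <- cbind(emb, matrix(0, nrow = nv, ncol = config$dimension - k))
  }
  rownames(emb) <- vocab

  word_vector_table(emb, provenance = list(
    algorithm = config$algorithm,
    dimension = config$dimension,
    window = config$window,
    min_count = config$min_count,
    seed = config$seed,
    n_lines = length(lines),
    n_vocab = nv
  ))
}

#' Look up token vectors, reporting out-of-vocabulary tokens
#'
#' @param table A [word_vector_table()].
#' @param tokens Character vector of tokens.
#' @return A numeric matrix of the in-vocabulary token vectors (one row
#'   per occurrence, in order) with attribute `oov` holding the
#'   out-of-vocabulary tokens.
#' @export
lookup_vectors <- function(table, tokens) {
  stopifnot(inherits(table, "word_vector_table"), is.character(tokens))
  idx <- match(tokens, rownames(table$vectors))
  oov <- tokens[is.na(idx)]
  mat <- table$vectors[idx[!is.na(idx)], , drop = FALSE]
  attr(mat, "oov") <- oov
  mat
}

#' Whole-sentence encoder adapter
#'
#' Contract for externally trained sentence-embedding models (paragraph
#' vectors, sent2vec-style models, RNN sentence encoders): a deterministic
#' function from a token vector to a fixed-length numeric vector. The
#' adapter validates the declared dimension on every call.
#'
#' @param encode A function taking a character vector of tokens and
#'   returning a numeric vector of length `dimension`.
#' @param dimension Positive integer output dimension.
#' @param provenance Free-text or list description of the wrapped model.
#' @return An object of class `sentence_encoder`.
#' @export
sentence_encoder <- function(encode, dimension, provenance = "") {
  stopifnot(is.function(encode))
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 1L) {
    stop("'dimension' must be a positive integer", call. = FALSE)
  }
  structure(list(encode = encode, dimension = dimension, provenance = provenance),
            class = "sentence_encoder")
}

#' @export
print.sentence_encoder <- function(x, ...) {
  cat("Sentence encoder:", x$dimension, "dimensions\n")
  if (is.character(x$provenance) && nzchar(x$provenance[1L])) {
    cat("  provenance:", x$provenance[1L], "\n")
  }
  invisible(x)
}

#' Encode a tokenized sentence as one vector
#'
#' For a [word_vector_table()], looks up each token and pools the
#' in-vocabulary vectors with the requested strategy; out-of-vocabulary
#' tokens are skipped and their count attached as attribute `oov_count`.
#' For a [sentence_encoder()], delegates to the wrapped model. A sentence
#' whose tokens are all out of vocabulary cannot be encoded and raises an
#' error, which evaluation layers surface as a missing score.
#'
#' @param model A `word_vector_table` or `sentence_encoder`.
#' @param tokens Non-empty character vector of tokens.
#' @param pooling Pooling strategy for word tables; see [pool_vectors()].
#' @return Numeric vector of length `model$dimension`.
#' @export
encode_sentence <- function(model, tokens, pooling = "max") {
  UseMethod("encode_sentence")
}

#' @export
encode_sentence.word_vector_table <- function(model, tokens, pooling = "max") {
  if (!length(tokens)) stop("cannot encode an empty sentence", call. = FALSE)
  mat <- lookup_vectors(model, tokens)
  oov <- attr(mat, "oov")
  if (nrow(mat) == 0L) {
    stop("all ", length(tokens), " tokens are out of vocabulary", call. = FALSE)
  }
  out <- pool_vectors(mat, pooling)
  attr(out, "oov_count") <- length(oov)
  out
}

#' @export
encode_sentence.sentence_encoder <- function(model, tokens, pooling = "max") {
  if (!length(tokens)) stop("cannot encode an empty sentence", call. = FALSE)
  out <- model$encode(tokens)
  if (!is.numeric(out) || length(out) != model$dimension) {
    stop("encoder returned a vector of length ", length(out),
         ", expected ", model$dimension, call. = FALSE)
  }
  attr(out, "oov_count") <- 0L
  out
}

#' Read and write word vectors in the standard text format
#'
#' The plain-text interchange format used by word-embedding tools: a
#' header line `"<vocab_size> <dimension>"`, then one line per token with
#' the token followed by its whitespace-separated vector components.
#'
#' @param path File path.
#' @return `read_word_vectors()` returns a [word_vector_table()];
#'   `write_word_vectors()` returns `path` invisibly.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty vector file: ", path, call. = FALSE)
  header <- suppressWarnings(
    as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]))
  if (length(header) != 2L || anyNA(header)) {
    stop("malformed header line in ", path, call. = FALSE)
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) != header[1L]) {
    stop("vector file declares ", header[1L], " tokens but has ", length(body),
         call. = FALSE)
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(header[2L])))
  rownames(mat) <- tokens
  word_vector_table(mat, provenance = list(source = path))
}

#' @rdname read_word_vectors
#' @param table A [word_vector_table()].
#' @export
write_word_vectors <- function(table, path) {
  stopifnot(inherits(table, "word_vector_table"))
  mat <- table$vectors
  header <- paste(nrow(mat), ncol(mat))
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i], paste(format(mat[i, ], digits = 17, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}
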