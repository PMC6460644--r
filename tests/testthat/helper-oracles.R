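# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: naive loops and textbook formulas only.

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

oracle_qgrams <- function(s, q) {
  n <- nchar(s)
  if (n < q) return(character(0))
  out <- character(n - q + 1)
  for (i in seq_len(n - q + 1)) out[i] <- substr(s, i, i + q - 1)
  out
}

# directed q-gram similarity with one-to-one gram matching, O(n*m)
oracle_qgram_sim <- function(s1, s2, q) {
  g1 <- oracle_qgrams(s1, q)
  g2 <- oracle_qgrams(s2, q)
  if (!length(g1)) return(0)
  used <- rep(FALSE, length(g2))
  matches <- 0
  for (g in g1) {
    for (j in seq_along(g2)) {
      if (!used[j] && g2[j] == g) {
        used[j] <- TRUE
        matches <- matches + 1
        break
      }
    }
  }
  matches / length(g1)
}

oracle_pool <- function(vectors, strategy) {
  d <- length(vectors[[1]])
  out <- numeric(d)
  for (k in seq_len(d)) {
    vals <- vapply(vectors, function(v) v[k], numeric(1))
    out[k] <- switch(strategy,
                     max = max(vals), min = min(vals),
                     sum = sum(vals), mean = sum(vals) / length(vals))
  }
  out
}

oracle_cosine <- function(u, v) {
  sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# mid-ranks by explicit tie averaging, then the Pearson formula
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# OLS by explicit normal equations (X'X)^{-1} X'y
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# minimal independent preprocessing used where a test recomputes token
# sets without going through the package pipeline
oracle_tokens <- function(sentence, stopwords) {
  x <- tolower(sentence)
  x <- gsub("[.,:;?!/]", " ", x)
  x <- gsub("-", " ", x)
  toks <- strsplit(trimws(gsub("[[:space:]]+", " ", x)), " ")[[1]]
  toks[!(toks %in% stopwords)]
}

random_token_set <- function(n_max = 8) {
  pool <- c("alpha", "beta", "gamma", "delta", "kinase", "tumour", "cell",
            "pathway", "ras", "rip1", "rip3", "mir146a", "tet2", "senescence")
  sample(pool, sample.int(n_max, 1))
}

random_string <- function(len_range = c(0, 15)) {
  n <- sample(seq(len_range[1], len_range[2]), 1)
  paste(sample(letters[1:6], n, replace = TRUE), collapse = "")
}
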