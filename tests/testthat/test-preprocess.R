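test_that("sentence segmentation splits on terminal punctuation", {
  doc <- "Rip1 was reported to interact with rip3. Moreover, other reports exist."
  sents <- segment_sentences(doc)
  expect_length(sents, 2)
  expect_equal(sents[1], "Rip1 was reported to interact with rip3.")

  expect_length(segment_sentences("one sentence"), 1)
  expect_length(tokenize_sentence("one sentence"), 2)
  expect_identical(segment_sentences(""), character(0))
  expect_identical(segment_sentences("   "), character(0))
  expect_error(segment_sentences(c("a", "b")), "single character")
})

test_that("segmentation respects abbreviations, matching a hand-segmented oracle", {
  doc <- paste(
    "Necroptosis is regulated by rip1, e.g. in tumour cells.",
    "As shown in Fig. 2, expression was reduced.",
    "Samwald et al. reported similar findings.",
    "The effect was strong (p < 0.01).",
    "Finally, tet2 depletion impaired differentiation."
  )
  hand_segmented <- c(
    "Necroptosis is regulated by rip1, e.g. in tumour cells.",
    "As shown in Fig. 2, expression was reduced.",
    "Samwald et al. reported similar findings.",
    "The effect was strong (p < 0.01).",
    "Finally, tet2 depletion impaired differentiation."
  )
  expect_identical(segment_sentences(doc), hand_segmented)
})

test_that("segmentation partitions the document's non-whitespace content", {
  docs <- c(
    "First sentence. Second one! Third? Yes.",
    "No boundary here at all",
    "Values were 3.5 or higher. Next sentence follows."
  )
  for (doc in docs) {
    sents <- segment_sentences(doc)
    expect_identical(gsub("[[:space:]]", "", paste(sents, collapse = "")),
                     gsub("[[:space:]]", "", doc))
    expect_true(all(vapply(sents, function(s)
      length(tokenize_sentence(s)) >= 1, logical(1))))
  }
})

test_that("long-line filter applies a strict < threshold and is idempotent", {
  cfg <- preprocess_config(max_line_chars = 200)
  l199 <- strrep("a", 199)
  l200 <- strrep("a", 200)
  expect_identical(filter_long_lines(c(l199, l200), cfg), l199)

  set.seed(42)
  lines <- vapply(sample(1:400, 1000, replace = TRUE),
                  function(n) strrep("x", n), character(1))
  kept <- filter_long_lines(lines, cfg)
  # brute-force recount
  expect_length(kept, sum(vapply(lines, nchar, integer(1)) < 200))
  expect_identical(filter_long_lines(kept, cfg), kept)
  # order preserved, subsequence of input
  expect_true(all(kept %in% lines))
})

test_that("hyphen splitting matches the word-boundary rule and conserves characters", {
  expect_identical(split_hyphens("anti-HER2 therapies"), "anti HER2 therapies")
  expect_identical(split_hyphens("well known"), "well known")
  expect_identical(split_hyphens("rnai-mediated tet2 knock-down"),
                   "rnai mediated tet2 knock down")
  # leading/trailing hyphens are stripped, not spaced
  expect_identical(split_hyphens("-start mid- -end"), "start mid end")
  # oracle: regex split on hyphen between word characters
  set.seed(7)
  for (i in 1:50) {
    words <- replicate(5, paste(sample(c(letters, 0:9), 4), collapse = ""))
    s <- paste(words[1], "-", paste0(words[2], "-", words[3]), words[4],
               paste0(words[5], "-"))
    out <- split_hyphens(s)
    expect_false(grepl("[[:alnum:]]-[[:alnum:]]", out))
    strip <- function(x) sort(strsplit(gsub("[-[:space:]]", "", x), "")[[1]])
    expect_identical(strip(out), strip(s))
  }
})

test_that("stopword and punctuation removal keeps an ordered subset", {
  cfg <- preprocess_config()
  expect_identical(remove_stopwords(c("the", "expression", "of", "mir146a"), cfg),
                   c("expression", "mir146a"))
  expect_identical(remove_stopwords(character(0), cfg), character(0))
  expect_identical(remove_stopwords(c("the", "of", "and"), cfg), character(0))
  expect_identical(remove_stopwords(c("THE", "Expression"), cfg), "Expression")
  expect_identical(remove_stopwords(c("rip1", ".", ",", "rip3"), cfg),
                   c("rip1", "rip3"))

  set.seed(11)
  for (i in 1:20) {
    toks <- sample(c("the", "a", "of", "kinase", "tumour", ".", "cell"),
                   10, replace = TRUE)
    out <- remove_stopwords(toks, cfg)
    # output token multiset is contained in the input token multiset
    expect_true(all(table(out) <= table(toks)[names(table(out))]))
    # membership oracle against the configured lists
    expect_false(any(tolower(out) %in% cfg$stopwords))
    expect_false(any(out %in% cfg$punctuation))
  }
})

test_that("build_corpus counts sentences, filters long lines, and reports stats", {
  docs <- c(
    "Alpha regulates beta. Beta binds gamma. Gamma is downstream.",
    "Delta was induced. Epsilon was suppressed. Zeta did not change. Eta rose.",
    "Theta fell. Iota was stable. Kappa interacts with lambda."
  )
  res <- build_corpus(docs)
  expect_equal(res$stats$n_lines, 10)
  expect_length(res$lines, 10)

  # one table-like 250-character line is filtered out
  docs_long <- c(docs, paste(rep("12345678", 32), collapse = " "))
  res2 <- build_corpus(docs_long)
  expect_equal(res2$stats$n_lines, 10)
  res3 <- build_corpus(docs_long, preprocess_config(max_line_chars = 500))
  expect_equal(res3$stats$n_lines, 11)

  expect_error(build_corpus(character(0)), "non-empty")
  expect_error(build_corpus("no/such/file.txt"), "no/such/file.txt")

  # stats agree with an independent naive recount
  toks <- unlist(strsplit(res$lines, " "))
  expect_equal(res$stats$n_tokens, length(toks))
  expect_equal(res$stats$n_unique_tokens, length(unique(toks)))
  expect_equal(res$stats$mean_line_length, mean(nchar(res$lines)))
  expect_equal(res$stats$max_line_length, max(nchar(res$lines)))
  expect_true(res$stats$max_line_length >= res$stats$mean_line_length)
})

test_that("build_corpus reads documents from files and writes one sentence per line", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "doc1.txt")
  writeLines("Alpha regulates beta. Beta binds gamma.", f1)
  out <- file.path(dir, "corpus.txt")
  res <- build_corpus(f1, output = out)
  expect_identical(readLines(out), res$lines)
  expect_equal(res$stats$n_lines, 2)
})

test_that("segment_and_tokenize returns raw strings alongside tokens", {
  sents <- segment_and_tokenize("Rip1 binds rip3. It does so strongly.")
  expect_length(sents, 2)
  expect_s3_class(sents[[1]], "tokenized_sentence")
  expect_identical(sents[[1]]$raw, "Rip1 binds rip3.")
  expect_identical(sents[[1]]$tokens, c("rip1", "binds", "rip3", "."))
  expect_identical(segment_and_tokenize(""), list())
})
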