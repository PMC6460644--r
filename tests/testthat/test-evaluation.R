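test_that("benchmarks round-trip losslessly through the TSV dialect", {
  b <- generate_benchmark(fixture_config(benchmark_size = 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(b, path)
  back <- read_benchmark(path)
  expect_equal(nrow(back), 25)
  expect_identical(back$pair_id, b$pair_id)
  expect_identical(back$sentence1, b$sentence1)
  expect_identical(back$sentence2, b$sentence2)
  expect_equal(back$gold, b$gold, tolerance = 1e-15)
  expect_identical(back$subset, b$subset)

  # pairs without gold (contradiction subsets) survive the round trip
  neg <- generate_negation_pairs(
    generate_statement_sentences(fixture_config(), 5, "negation"))
  write_benchmark(neg, path)
  back2 <- read_benchmark(path)
  expect_true(all(is.na(back2$gold)))
  expect_identical(back2$subset, rep("negation", nrow(neg)))
})

test_that("benchmark reading rejects malformed rows with their row number", {
  path <- withr::local_tempfile()
  writeLines(c("pair_id\tsentence1\tsentence2\tscore\tsubset",
               "p1\tfoo bar\tbaz qux\t4.3\tmain"), path)
  expect_error(read_benchmark(path), "outside \\[0, 4\\].*row 2")

  writeLines(c("pair_id\tsentence1\tsentence2\tscore\tsubset",
               "p1\tfoo\tbar\t2.0\tmain",
               "p2\tonly two fields"), path)
  expect_error(read_benchmark(path), "row 3")

  writeLines(c("pair_id\tsentence1\tsentence2\tscore\tsubset",
               "p1\tfoo\tbar\tnot_a_number\tmain"), path)
  expect_error(read_benchmark(path), "not numeric")

  writeLines("wrong\theader", path)
  expect_error(read_benchmark(path), "header")
})

test_that("pearson and spearman match textbook-formula oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)
  expect_equal(spearman_cor(x, rev(x)), -1.0)
  # strictly monotone nonlinear transform: r_s stays exactly 1
  expect_equal(spearman_cor(x, exp(x)), 1.0)

  set.seed(47)
  for (i in 1:50) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(length(a))
    expect_equal(pearson_cor(a, b), oracle_pearson(a, b), tolerance = 1e-12)
    expect_equal(spearman_cor(a, b), oracle_spearman(a, b), tolerance = 1e-12)
    # spearman invariant under strictly monotone transforms of either side
    expect_equal(spearman_cor(exp(a), b), spearman_cor(a, b), tolerance = 1e-12)
  }
})

test_that("spearman uses mid-ranks for ties", {
  x <- c(1, 2, 2, 3, 3, 3, 4)
  y <- c(2, 1, 4, 4, 5, 7, 7)
  expect_equal(spearman_cor(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(spearman_cor(x, y), pearson_cor(oracle_midrank(x), oracle_midrank(y)),
               tolerance = 1e-12)
})

test_that("undefined correlations raise errors instead of returning NA", {
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_cor(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_cor(c(1, 2, NA), c(1, 2, 3)), "missing")
})

test_that("evaluate_scorer correlates predictions with gold and tracks missing", {
  b <- generate_benchmark(fixture_config(benchmark_size = 30))

  gold_lookup <- stats::setNames(b$gold, paste(b$sentence1, b$sentence2))
  oracle_scorer <- function(s1, s2) gold_lookup[[paste(s1, s2)]]
  rep1 <- evaluate_scorer(oracle_scorer, b, name = "gold-echo")
  expect_equal(rep1$pearson_r, 1.0)
  expect_equal(rep1$spearman_rs, 1.0)
  expect_equal(rep1$n_missing, 0)

  expect_error(evaluate_scorer(function(s1, s2) 0.5, b), "zero variance")

  # failures on some pairs are excluded and counted, never imputed
  bad <- paste(b$sentence1, b$sentence2)[1:5]
  flaky <- function(s1, s2) {
    if (paste(s1, s2) %in% bad) stop("boom")
    oracle_scorer(s1, s2)
  }
  rep2 <- evaluate_scorer(flaky, b, name = "flaky")
  expect_equal(rep2$n_missing, 5)
  expect_equal(rep2$pearson_r, 1.0)
  expect_error(evaluate_scorer(function(s1, s2) stop("dead"), b), "50%")
})

test_that("the Jaccard scorer on a fixture matches per-pair recomputation", {
  cfg <- preprocess_config()
  b <- generate_benchmark(fixture_config(seed = 3, benchmark_size = 20))
  rep <- evaluate_scorer(jaccard_scorer(cfg), b)
  manual <- vapply(seq_len(nrow(b)), function(i) {
    oracle_jaccard(oracle_tokens(b$sentence1[i], cfg$stopwords),
                   oracle_tokens(b$sentence2[i], cfg$stopwords))
  }, numeric(1))
  expect_equal(rep$predicted, manual, tolerance = 1e-15)
  expect_equal(rep$pearson_r, oracle_pearson(manual, b$gold), tolerance = 1e-12)
})

test_that("the high-similarity threshold is inclusive at 3.5", {
  b <- data.frame(
    pair_id = c("p1", "p2", "p3", "p4"),
    sentence1 = "s", sentence2 = "t",
    gold = c(3.5, 3.49, 4.0, 0.2),
    subset = "main", stringsAsFactors = FALSE
  )
  sel <- select_high_similarity(b)
  expect_identical(sel$pair_id, c("p1", "p3"))

  big <- generate_benchmark(fixture_config(seed = 8))
  sel2 <- select_high_similarity(big, threshold = 2.0)
  expect_equal(nrow(sel2), sum(big$gold >= 2.0))   # brute-force threshold scan
  expect_identical(sel2$pair_id, big$pair_id[big$gold >= 2.0])
})

test_that("the contradiction probe reports per-subset means and the ordering flag", {
  cfg <- fixture_config()
  neg <- generate_negation_pairs(generate_statement_sentences(cfg, 6, "negation"))
  sim <- generate_similar_pairs(cfg, 5)
  subsets <- list(high_similarity = sim, negation = neg)

  # degenerate scorer: every pair maps to the same vector, all means 1
  constant <- function(s1, s2) cosine_similarity(c(1, 1), c(1, 1))
  rep1 <- contradiction_probe(constant, subsets)
  expect_equal(as.numeric(rep1$means), rep(1, length(rep1$means)),
               tolerance = 1e-12)
  expect_false(any(rep1$ordering_flag))

  # constructed scorer: negated pairs orthogonal, others identical
  constructed <- function(s1, s2) {
    if (grepl("\\bnot\\b", s2)) cosine_similarity(c(1, 0), c(0, 1)) else 1
  }
  rep2 <- contradiction_probe(constructed, subsets)
  expect_equal(unname(rep2$means[1, "negation"]), 0)
  expect_true(all(rep2$ordering_flag))

  # scorer failures skip the pair and are counted
  half_dead <- function(s1, s2) {
    if (grepl("\\bnot\\b", s2)) stop("nope") else 0.5
  }
  rep3 <- contradiction_probe(half_dead,
                              list(high_similarity = sim, negation = sim))
  expect_equal(unname(rep3$skipped[1, "negation"]), 0)
  expect_error(contradiction_probe(half_dead, list(negation = neg)), "every pair")
  expect_error(contradiction_probe(constant, list(a = sim[0, ])), "empty")
})

test_that("lexical-overlap scoring rates contradiction pairs above similar pairs", {
  cfg <- fixture_config()
  neg <- generate_negation_pairs(generate_statement_sentences(cfg, 13, "negation"))
  ant <- generate_antonym_pairs(generate_statement_sentences(cfg, 7, "antonym"))
  sim <- generate_similar_pairs(cfg, 11)
  rep <- contradiction_probe(
    list(bow = bow_scorer()),
    list(high_similarity = sim, negation = neg, antonym = ant)
  )
  expect_gt(rep$means["bow", "negation"], rep$means["bow", "high_similarity"])
  expect_gt(rep$means["bow", "antonym"], rep$means["bow", "high_similarity"])
  expect_false(rep$ordering_flag[["bow"]])
})
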