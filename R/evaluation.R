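#' Read and write sentence-pair benchmarks
#'
#' The benchmark dialect is a UTF-8 tab-separated file with a header row
#' and columns `pair_id`, `sentence1`, `sentence2`, `score` and an
#' optional `subset` label (`main`, `negation`, `antonym`,
#' `high_similarity`). Gold scores live on the continuous 0-4 annotation
#' scale (0 = no relation, 4 = semantically equivalent) and may be empty
#' for unannotated pairs. Reading and writing round-trip losslessly.
#'
#' @param path File path.
#' @return `read_benchmark()` returns a data frame with columns
#'   `pair_id`, `sentence1`, `sentence2`, `gold` (numeric, `NA` when
#'   absent) and `subset` (character, `NA` when absent).
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty benchmark file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("pair_id", "sentence1", "sentence2", "score")
  if (!all(required %in% header)) {
    stop("benchmark header must contain: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines[-1L]), function(i) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) > length(header) || length(fields) < 3L) {
      stop("malformed benchmark row ", i + 1L, " in ", path, call. = FALSE)
    }
    length(fields) <- length(header)   # pad trailing empty fields
    names(fields) <- header
    fields
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  gold_raw <- tab$score
  gold <- suppressWarnings(as.numeric(gold_raw))
  bad_parse <- which(!is.na(gold_raw) & nzchar(gold_raw) & is.na(gold))
  if (length(bad_parse)) {
    stop("malformed benchmark row ", bad_parse[1L] + 1L,
         ": gold score is not numeric", call. = FALSE)
  }
  out_of_range <- which(!is.na(gold) & (gold < 0 | gold > 4))
  if (length(out_of_range)) {
    stop("gold score outside [0, 4] at row ", out_of_range[1L] + 1L,
         " (value ", gold[out_of_range[1L]], ")", call. = FALSE)
  }
  if (any(is.na(tab$sentence1) | !nzchar(tab$sentence1)) ||
      any(is.na(tab$sentence2) | !nzchar(tab$sentence2))) {
    stop("benchmark contains an empty sentence", call. = FALSE)
  }
  data.frame(
    pair_id = tab$pair_id,
    sentence1 = tab$sentence1,
    sentence2 = tab$sentence2,
    gold = gold,
    subset = if ("subset" %in% header) {
      ifelse(is.na(tab$subset) | !nzchar(tab$subset), NA_character_, tab$subset)
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
}

#' @rdname read_benchmark
#' @param benchmark A benchmark data frame as returned by
#'   [read_benchmark()] or [generate_benchmark()].
#' @export
write_benchmark <- function(benchmark, path) {
  required <- c("pair_id", "sentence1", "sentence2", "gold")
  if (!all(required %in% names(benchmark))) {
    stop("benchmark must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  subset <- if ("subset" %in% names(benchmark)) benchmark$subset else NA_character_
  fmt_gold <- ifelse(is.na(benchmark$gold), "",
                     format(benchmark$gold, digits = 17, trim = TRUE,
                            scientific = FALSE))
  lines <- c(
    "pair_id\tsentence1\tsentence2\tscore\tsubset",
    paste(benchmark$pair_id, benchmark$sentence1, benchmark$sentence2,
          fmt_gold, ifelse(is.na(subset), "", subset), sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

check_cor_args <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric", call. = FALSE)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed here", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used by the evaluation harness; errors (rather
#' than returning `NA`) on fewer than three observations or a
#' zero-variance argument, where the correlation is undefined.
#'
#' @param x,y Equal-length numeric vectors without missing values.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  check_cor_args(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (ties receive average ranks).
#' Invariant under strictly monotone transforms of either argument.
#'
#' @inheritParams pearson_cor
#' @return The rank correlation coefficient in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  check_cor_args(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Evaluate a pair scorer against gold annotations
#'
#' Applies a scoring function to every benchmark pair and reports Pearson
#' and Spearman correlation between the predicted scores and the averaged
#' expert gold scores. A pair for which the scorer fails or returns `NA`
#' (for example, every token out of vocabulary) is excluded from the
#' correlations and counted in `n_missing` — missing scores are never
#' imputed. More than 50% missing pairs renders the report meaningless
#' and raises an error.
#'
#' @param scorer A function `(sentence1, sentence2) -> numeric score`,
#'   e.g. from [jaccard_scorer()], [qgram_scorer()],
#'   [embedding_scorer()] or [bow_scorer()].
#' @param benchmark A benchmark data frame (see [read_benchmark()]) whose
#'   pairs carry gold scores.
#' @param name Metric name recorded in the report (defaults to the
#'   scorer's `metric` attribute, if any).
#' @return An object of class `sim_eval`: `metric_name`, `n_pairs`,
#'   `predicted` (per-pair scores, `NA` where missing), `pearson_r`,
#'   `spearman_rs`, `n_missing`.
#' @export
evaluate_scorer <- function(scorer, benchmark, name = NULL) {
  stopifnot(is.function(scorer), is.data.frame(benchmark))
  if (is.null(name)) {
    name <- attr(scorer, "metric")
    if (is.null(name)) name <- "scorer"
  }
  if (anyNA(benchmark$gold)) {
    stop("every benchmark pair must carry a gold score", call. = FALSE)
  }
  predicted <- vapply(seq_len(nrow(benchmark)), function(i) {
    tryCatch(
      as.numeric(scorer(benchmark$sentence1[i], benchmark$sentence2[i]))[1L],
      error = function(e) NA_real_
    )
  }, numeric(1))
  ok <- !is.na(predicted)
  if (sum(!ok) > nrow(benchmark) / 2) {
    stop("more than 50% of pairs unscored (", sum(!ok), " of ",
         nrow(benchmark), "); report would be meaningless", call. = FALSE)
  }
  structure(
    list(
      metric_name = name,
      n_pairs = nrow(benchmark),
      predicted = predicted,
      gold = benchmark$gold,
      pearson_r = pearson_cor(predicted[ok], benchmark$gold[ok]),
      spearman_rs = spearman_cor(predicted[ok], benchmark$gold[ok]),
      n_missing = sum(!ok)
    ),
    class = "sim_eval"
  )
}

#' @export
print.sim_eval <- function(x, ...) {
  cat("Intrinsic evaluation:", x$metric_name, "\n")
  cat("  pairs:", x$n_pairs,
      if (x$n_missing) paste0("(", x$n_missing, " unscored)") else "", "\n")
  cat(sprintf("  Pearson r:    %.4f\n", x$pearson_r))
  cat(sprintf("  Spearman r_s: %.4f\n", x$spearman_rs))
  invisible(x)
}

#' Select the highly similar benchmark subset
#'
#' Pairs whose gold score reaches the threshold, inclusively: a pair
#' rated exactly 3.5 is part of the default high-similarity subset.
#' Order is preserved.
#'
#' @param benchmark A benchmark data frame with gold scores.
#' @param threshold Inclusive gold-score cutoff (default 3.5).
#' @return The subset of rows with `gold >= threshold`.
#' @export
select_high_similarity <- function(benchmark, threshold = 3.5) {
  stopifnot(is.data.frame(benchmark))
  if (anyNA(benchmark$gold)) {
    stop("gold scores must be present for subset selection", call. = FALSE)
  }
  benchmark[benchmark$gold >= threshold, , drop = FALSE]
}

#' Contradiction probe: subset mean similarities per scorer
#'
#' For each scorer and each sentence-pair subset (typically negation and
#' antonym contradiction pairs plus a highly similar reference subset),
#' computes the mean predicted similarity. A model that understood
#' contradiction would score the high-similarity subset above the
#' contradiction subsets; `ordering_flag` records, per scorer, whether
#' that expected ordering holds. Lexical-overlap models typically show
#' the reverse, because contradiction pairs share almost all their
#' tokens. No significance testing is performed: the subsets are far too
#' small for a meaningful test.
#'
#' @param scorers A named list of scoring functions
#'   `(sentence1, sentence2) -> score`, or a single function.
#' @param subsets A named list of non-empty benchmark data frames, e.g.
#'   `list(high_similarity = ..., negation = ..., antonym = ...)`.
#' @param high_label Name of the reference subset used for the ordering
#'   flag.
#' @return An object of class `contradiction_report`: `means` (scorer x
#'   subset matrix), `sizes`, `skipped` (pairs a scorer failed on, per
#'   cell), `ordering_flag` (named logical per scorer).
#' @export
contradiction_probe <- function(scorers, subsets, high_label = "high_similarity") {
  if (is.function(scorers)) scorers <- list(scorer = scorers)
  stopifnot(is.list(scorers), length(scorers) >= 1L,
            is.list(subsets), length(subsets) >= 1L)
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    stop("'subsets' must be a named list", call. = FALSE)
  }
  for (nm in names(subsets)) {
    if (!is.data.frame(subsets[[nm]]) || nrow(subsets[[nm]]) == 0L) {
      stop("subset '", nm, "' is empty", call. = FALSE)
    }
  }
  if (is.null(names(scorers))) names(scorers) <- paste0("scorer", seq_along(scorers))

  means <- matrix(NA_real_, nrow = length(scorers), ncol = length(subsets),
                  dimnames = list(names(scorers), names(subsets)))
  skipped <- means
  for (s in names(scorers)) {
    for (g in names(subsets)) {
      b <- subsets[[g]]
      vals <- vapply(seq_len(nrow(b)), function(i) {
        tryCatch(as.numeric(scorers[[s]](b$sentence1[i], b$sentence2[i]))[1L],
                 error = function(e) NA_real_)
      }, numeric(1))
      if (all(is.na(vals))) {
        stop("scorer '", s, "' failed on every pair of subset '", g, "'",
             call. = FALSE)
      }
      means[s, g] <- mean(vals, na.rm = TRUE)
      skipped[s, g] <- sum(is.na(vals))
    }
  }
  ordering_flag <- if (high_label %in% colnames(means)) {
    others <- setdiff(colnames(means), high_label)
    apply(means, 1L, function(row) all(row[high_label] > row[others]))
  } else {
    stats::setNames(rep(NA, nrow(means)), rownames(means))
  }
  structure(
    list(
      means = means,
      sizes = vapply(subsets, nrow, integer(1)),
      skipped = skipped,
      ordering_flag = ordering_flag,
      high_label = high_label
    ),
    class = "contradiction_report"
  )
}

#' @export
print.contradiction_report <- function(x, ...) {
  cat("Contradiction probe: mean similarity per subset\n")
  cat("  subset sizes:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n\n")
  print(round(x$means, 4))
  cat("\nExpected ordering (", x$high_label,
      " above all contradiction subsets):\n", sep = "")
  for (s in rownames(x$means)) {
    cat("  ", s, ": ", if (isTRUE(x$ordering_flag[[s]])) "holds" else "violated",
        "\n", sep = "")
  }
  invisible(x)
}
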