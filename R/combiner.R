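#' Unsupervised hybrid score: the mean of several similarity features
#'
#' Combines per-pair similarity scores from several metrics by taking
#' their arithmetic mean. The result always lies between the smallest and
#' largest feature value and is invariant to feature order.
#'
#' @param features Numeric vector of scores for one pair, or a numeric
#'   matrix / data frame (one row per pair, one column per metric).
#' @return A single score, or one score per row for matrix input.
#' @examples
#' unsupervised_mean(c(jaccard = 0.2, qgram = 0.4, cosine = 0.6, encoder = 0.8))
#' @export
unsupervised_mean <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.matrix(features)) {
    if (ncol(features) < 1L || nrow(features) < 1L) {
      stop("empty feature set", call. = FALSE)
    }
    if (!all(is.finite(features))) stop("all features must be finite", call. = FALSE)
    return(rowMeans(features))
  }
  if (!is.numeric(features) || !length(features)) {
    stop("empty feature set", call. = FALSE)
  }
  if (!all(is.finite(features))) stop("all features must be finite", call. = FALSE)
  mean(features)
}

#' Named feature presets for the score combiners
#'
#' Two shipped configurations: `"supervised"` — the feature set of the
#' linear-regression combiner (Jaccard, q-gram, and cosine scores from a
#' sent2vec-style encoder, a distributed-memory paragraph-vector encoder,
#' an RNN sentence encoder and a pooled word-vector table); `"hybrid"` —
#' the unsupervised-mean configuration (Jaccard, q-gram, and cosine scores
#' from a distributed-bag-of-words paragraph-vector encoder and a
#' sent2vec-style encoder). The names label columns of a feature table;
#' any encoder satisfying the adapter contracts can stand behind them.
#'
#' @return Named list of character vectors of feature names.
#' @export
combiner_presets <- function() {
  list(
    supervised = c("jaccard", "qgram", "sent2vec_cosine", "pv_dm_cosine",
                   "skip_thoughts_cosine", "fasttext_cosine"),
    hybrid = c("jaccard", "qgram", "pv_dbow_cosine", "sent2vec_cosine")
  )
}

#' Fit the supervised linear score combiner
#'
#' Ordinary least squares of the gold similarity score on the per-pair
#' similarity features: \eqn{y = b_0 + \sum_j b_j x_j}. No
#' regularization is applied. Optionally also produces k-fold
#' cross-validated predictions (fixed fold seed), reported separately from
#' the in-sample fit so the two are never conflated.
#'
#' @param features Numeric matrix or data frame of similarity scores, one
#'   row per sentence pair, one named column per metric.
#' @param gold Numeric vector of gold similarity scores on the 0-4 scale
#'   (any non-constant numeric response is accepted).
#' @param cv Number of cross-validation folds; 0 (default) disables
#'   cross-validation, otherwise `cv >= 2`.
#' @param seed Integer seed fixing the fold assignment.
#' @return An object of class `sim_combiner` with components `intercept`,
#'   `coefficients` (named by feature), `feature_order`, `fitted.values`,
#'   `residuals`, `gold`, `n`, and — when `cv > 0` — `cv` (a list with the
#'   fold count, seed, and out-of-fold `predictions`). Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`.
#' @examples
#' x <- cbind(a = runif(30), b = runif(30))
#' y <- 1.5 + 2 * x[, "a"] - 0.5 * x[, "b"]
#' fit <- fit_combiner(x, y)
#' coef(fit)
#' @export
fit_combiner <- function(features, gold, cv = 0L, seed = 1L) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("'features' must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  k <- ncol(features)
  n <- nrow(features)
  if (k < 1L) stop("at least one feature is required", call. = FALSE)
  if (length(gold) != n) stop("'gold' must have one value per row", call. = FALSE)
  if (!all(is.finite(features)) || !all(is.finite(gold))) {
    stop("features and gold scores must be finite", call. = FALSE)
  }
  if (n < k + 2L) {
    stop("need at least k + 2 = ", k + 2L, " training rows, got ", n, call. = FALSE)
  }
  if (stats::var(gold) == 0) {
    stop("degenerate gold scores: response is constant", call. = FALSE)
  }

  X <- cbind("(Intercept)" = 1, features)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("rank-deficient design: collinear feature(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, gold)
  fitted <- drop(X %*% coefs)

  obj <- structure(
    list(
      intercept = unname(coefs[1L]),
      coefficients = coefs[-1L],
      feature_order = colnames(features),
      fitted.values = fitted,
      residuals = gold - fitted,
      gold = gold,
      n = n,
      qr = qr_x,
      cv = NULL
    ),
    class = "sim_combiner"
  )

  cv <- as.integer(cv)
  if (cv > 0L) {
    if (cv < 2L) stop("'cv' must be 0 or >= 2", call. = FALSE)
    if (cv > n) stop("more folds than rows", call. = FALSE)
    folds <- with_seed(seed, sample(rep_len(seq_len(cv), n)))
    preds <- rep(NA_real_, n)
    for (f in seq_len(cv)) {
      hold <- folds == f
      Xf <- X[!hold, , drop = FALSE]
      cf <- qr.coef(qr(Xf), gold[!hold])
      cf[is.na(cf)] <- 0   # fold-local collinearity: drop the aliased column
      preds[hold] <- drop(X[hold, , drop = FALSE] %*% cf)
    }
    obj$cv <- list(folds = cv, seed = as.integer(seed),
                   fold_id = folds, predictions = preds)
  }
  obj
}

#' @export
print.sim_combiner <- function(x, ...) {
  cat("Supervised similarity combiner (ordinary least squares)\n")
  cat("  features:", paste(x$feature_order, collapse = ", "), "\n")
  cat("  n =", x$n, "\n")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  r_in <- stats::cor(x$fitted.values, x$gold)
  cat(sprintf("  in-sample Pearson r: %.4f\n", r_in))
  if (!is.null(x$cv)) {
    r_cv <- stats::cor(x$cv$predictions, x$gold)
    cat(sprintf("  %d-fold CV Pearson r: %.4f (seed %d)\n",
                x$cv$folds, r_cv, x$cv$seed))
  }
  invisible(x)
}

#' @export
coef.sim_combiner <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
fitted.sim_combiner <- function(object, ...) object$fitted.values

#' @export
residuals.sim_combiner <- function(object, ...) object$residuals

#' @export
summary.sim_combiner <- function(object, ...) {
  p <- length(object$feature_order) + 1L
  rss <- sum(object$residuals^2)
  df <- object$n - p
  sigma2 <- rss / df
  R <- qr.R(object$qr)
  xtx_inv <- chol2inv(R)
  se <- sqrt(diag(xtx_inv) * sigma2)
  est <- coef(object)
  tval <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  out <- list(
    coefficients = tab,
    sigma = sqrt(sigma2),
    df = df,
    r_insample = stats::cor(object$fitted.values, object$gold),
    r_cv = if (!is.null(object$cv)) stats::cor(object$cv$predictions, object$gold),
    cv_folds = if (!is.null(object$cv)) object$cv$folds
  )
  class(out) <- "summary.sim_combiner"
  out
}

#' @export
print.summary.sim_combiner <- function(x, ...) {
  cat("Supervised similarity combiner - OLS fit\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual std. error: %.4f on %d degrees of freedom\n",
              x$sigma, x$df))
  cat(sprintf("In-sample Pearson r: %.4f\n", x$r_insample))
  if (!is.null(x$r_cv)) {
    cat(sprintf("%d-fold CV Pearson r: %.4f\n", x$cv_folds, x$r_cv))
  }
  invisible(x)
}

#' Predict similarity scores from a fitted combiner
#'
#' Applies \eqn{b_0 + \sum_j b_j x_j} to new feature rows. The feature
#' names must match the model's feature order exactly; missing or extra
#' names raise an error that lists them.
#'
#' @param object A fitted [fit_combiner()] model.
#' @param newdata Named numeric vector (one pair) or matrix / data frame
#'   with one named column per model feature.
#' @param clip Clip predictions to the benchmark scale `[0, 4]`?
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.sim_combiner <- function(object, newdata, clip = FALSE, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    stop("'newdata' must carry feature names", call. = FALSE)
  }
  missing <- setdiff(object$feature_order, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_order)
  if (length(missing) || length(extra)) {
    stop("feature mismatch - missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  X <- newdata[, object$feature_order, drop = FALSE]
  out <- drop(object$intercept + X %*% object$coefficients)
  if (clip) out <- pmin(4, pmax(0, out))
  out
}

#' Serialize a fitted combiner to JSON and back
#'
#' The JSON carries the feature order, intercept, coefficients, and fit
#' metadata (n, cross-validation settings and seed), so a fitted model can
#' be stored and reloaded for prediction.
#'
#' @param object A fitted [fit_combiner()] model.
#' @param path File path.
#' @return `write_combiner()` returns `path` invisibly;
#'   `read_combiner()` returns a `sim_combiner` usable with `predict()`
#'   (fit internals such as residuals are not round-tripped).
#' @export
write_combiner <- function(object, path) {
  stopifnot(inherits(object, "sim_combiner"))
  payload <- list(
    feature_order = object$feature_order,
    intercept = object$intercept,
    coefficients = as.list(object$coefficients),
    n = object$n,
    cv = if (!is.null(object$cv)) {
      list(folds = object$cv$folds, seed = object$cv$seed)
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combiner
#' @export
read_combiner <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(payload$coefficients)
  structure(
    list(
      intercept = payload$intercept,
      coefficients = coefs[payload$feature_order],
      feature_order = payload$feature_order,
      fitted.values = NULL, residuals = NULL, gold = NULL,
      n = payload$n, qr = NULL, cv = NULL
    ),
    class = "sim_combiner"
  )
}
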