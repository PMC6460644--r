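#' Jaccard similarity of two token sets
#'
#' The Jaccard index over unique tokens: the size of the intersection of
#' the two sets divided by the size of their union,
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}. For sentence scoring, `A` and
#' `B` are the unique tokens of each sentence after stopword and
#' punctuation removal and case folding; the measure is symmetric and
#' invariant to token order and duplication.
#'
#' @param a,b Character vectors of tokens; duplicates are ignored.
#' @return A score in `[0, 1]`. When both sets are empty the score is
#'   defined as 0 and a warning is raised (the 0/0 case carries no
#'   information).
#' @examples
#' jaccard_similarity(c("rip1", "interact", "rip3"), c("rip1", "bind", "rip3"))
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  a <- unique(a)
  b <- unique(b)
  n_union <- length(union(a, b))
  if (n_union == 0L) {
    warning("both token sets are empty; Jaccard similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / n_union
}

#' Character q-gram profile of a string
#'
#' Enumerates the contiguous length-`q` character substrings of `s`, left
#' to right, with multiplicity. No padding is used, so a string shorter
#' than `q` has an empty profile and the profile size is
#' `max(0, nchar(s) - q + 1)`.
#'
#' @param s A length-one character string.
#' @param q Gram length, an integer `>= 1`.
#' @return Character vector of grams (each exactly `q` characters), in
#'   order of occurrence.
#' @examples
#' qgram_profile("abcd", 3)
#' @export
qgram_profile <- function(s, q = 3L) {
  stopifnot(is.character(s), length(s) == 1L)
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("'q' must be an integer >= 1", call. = FALSE)
  n <- nchar(s)
  if (n < q) return(character(0))
  starts <- seq_len(n - q + 1L)
  substring(s, starts, starts + q - 1L)
}

# Multiset intersection size: each gram occurrence matches at most once.
multiset_overlap <- function(x, y) {
  if (!length(x) || !length(y)) return(0L)
  tx <- table(x)
  ty <- table(y)
  shared <- intersect(names(tx), names(ty))
  if (!length(shared)) return(0L)
  sum(pmin(as.integer(tx[shared]), as.integer(ty[shared])))
}

#' q-gram similarity of two strings
#'
#' The number of q-gram matches between the two strings divided by the
#' number of q-grams of the first string, which acts as the reference:
#' the measure is asymmetric as defined. Matches are counted as a multiset
#' intersection, so each gram occurrence matches at most once. Character
#' trigrams (`q = 3`) are the default. `symmetrize = "mean"` averages the
#' two directed scores.
#'
#' Strings fed to q-gram scoring by the pipeline scorers are the
#' stopword-stripped, case-folded sentences re-joined with single spaces.
#'
#' @param s1,s2 Length-one character strings; `s1` is the reference.
#' @param q Gram length, an integer `>= 1`.
#' @param symmetrize `"none"` (the directed definition) or `"mean"`.
#' @return A score in `[0, 1]`; 0 (with a warning) when the reference
#'   profile is empty.
#' @examples
#' qgram_similarity("necroptosis", "necroptosis", q = 3)
#' qgram_similarity("abcdef", "xyzxyz", q = 3)
#' @export
qgram_similarity <- function(s1, s2, q = 3L, symmetrize = c("none", "mean")) {
  symmetrize <- match.arg(symmetrize)
  p1 <- qgram_profile(s1, q)
  p2 <- qgram_profile(s2, q)
  directed <- function(ref, other) {
    if (!length(ref)) {
      warning("reference string shorter than q; q-gram similarity defined as 0",
              call. = FALSE)
      return(0)
    }
    multiset_overlap(ref, other) / length(ref)
  }
  if (symmetrize == "none") {
    directed(p1, p2)
  } else {
    (directed(p1, p2) + directed(p2, p1)) / 2
  }
}
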