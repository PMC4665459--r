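# Typed count containers shared by all estimators.  Counts must be
# non-negative integers (the conjugate updates assume multinomial data);
# real-valued "counts" are rejected.

check_counts <- function(x, what) {
  if (!is.numeric(x) || anyNA(x))
    stop(what, ": counts must be numeric and non-missing", call. = FALSE)
  if (any(x < 0))
    stop(what, ": counts must be non-negative", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8))
    stop(what, ": counts must be integers", call. = FALSE)
  as.integer(round(x))
}

#' 2x2 classification table for one binary test
#'
#' Cell counts indexed (test score X, disease status D), with 0 meaning
#' negative / non-diseased and 1 positive / diseased.  `n01` is the number
#' of diseased subjects with a negative test.
#'
#' @param n00,n01,n10,n11 Non-negative integer counts; first subscript is
#'   the test score, second the disease status.
#' @return An object of class `count_table_2x2` holding a 2x2 integer
#'   matrix with rows `X=0`,`X=1` and columns `D=0`,`D=1`.
#' @examples
#' count_table_2x2(327, 208, 115, 818)
#' @export
count_table_2x2 <- function(n00, n01, n10, n11) {
  n <- check_counts(c(n00, n01, n10, n11), "count_table_2x2")
  if (sum(n) == 0) stop("count_table_2x2: total count must be positive", call. = FALSE)
  m <- matrix(n, 2, 2, byrow = TRUE,
              dimnames = list(c("X=0", "X=1"), c("D=0", "D=1")))
  structure(list(counts = m), class = "count_table_2x2")
}

#' @export
print.count_table_2x2 <- function(x, ...) {
  cat("2x2 test-by-disease table (n =", sum(x$counts), ")\n")
  print(x$counts)
  invisible(x)
}

#' Paired 2x2 tables for two binary tests applied to the same subjects
#'
#' One 2x2 table of (test1, test2) outcomes for the diseased subjects and
#' one for the non-diseased, as in a paired-modality comparison study.
#'
#' @param diseased,nondiseased 2x2 matrices of counts indexed
#'   (test1, test2), rows = test1 in 0,1, columns = test2 in 0,1.
#' @return An object of class `paired_binary_counts`.
#' @export
paired_binary_counts <- function(diseased, nondiseased) {
  as_tab <- function(m, what) {
    m <- matrix(check_counts(m, what), 2, 2,
                dimnames = list(c("T1=0", "T1=1"), c("T2=0", "T2=1")))
    if (sum(m) == 0) stop(what, ": total count must be positive", call. = FALSE)
    m
  }
  structure(list(diseased = as_tab(diseased, "paired diseased table"),
                 nondiseased = as_tab(nondiseased, "paired non-diseased table")),
            class = "paired_binary_counts")
}

#' @export
print.paired_binary_counts <- function(x, ...) {
  cat("Paired binary tests; diseased (n =", sum(x$diseased),
      "), non-diseased (n =", sum(x$nondiseased), ")\n")
  cat("Diseased:\n"); print(x$diseased)
  cat("Non-diseased:\n"); print(x$nondiseased)
  invisible(x)
}

#' Ordinal rating counts for diseased and non-diseased groups
#'
#' Per-category counts of an ordinal test score (category 1 = least
#' indicative of disease, category k = most indicative).
#'
#' @param diseased,nondiseased Integer count vectors of equal length
#'   `k >= 2`; each group total must be positive.
#' @return An object of class `ordinal_counts` with fields `k`,
#'   `diseased`, `nondiseased`.
#' @export
ordinal_counts <- function(diseased, nondiseased) {
  d <- check_counts(diseased, "ordinal_counts diseased")
  nd <- check_counts(nondiseased, "ordinal_counts nondiseased")
  if (length(d) != length(nd))
    stop("ordinal_counts: groups must have the same number of categories", call. = FALSE)
  if (length(d) < 2) stop("ordinal_counts: need k >= 2 categories", call. = FALSE)
  if (sum(d) == 0 || sum(nd) == 0)
    stop("ordinal_counts: each group total must be positive", call. = FALSE)
  structure(list(k = length(d), diseased = d, nondiseased = nd),
            class = "ordinal_counts")
}

#' @export
print.ordinal_counts <- function(x, ...) {
  cat("Ordinal test counts,", x$k, "categories\n")
  print(rbind(diseased = x$diseased, nondiseased = x$nondiseased))
  invisible(x)
}

#' Counts from a verification-bias study
#'
#' For each test result category i: `s[i]` verified diseased, `r[i]`
#' verified non-diseased, and `u[i]` unverified subjects.  Categories are
#' ordered ascending in indication of disease; for a binary test `k = 2`
#' with category 1 = negative (Y=0) and category 2 = positive (Y=1).
#'
#' @param s,r,u Integer count vectors of equal length `k`.
#' @return An object of class `verification_counts` with derived column
#'   totals `m = s + r + u`.
#' @export
verification_counts <- function(s, r, u) {
  s <- check_counts(s, "verification_counts s")
  r <- check_counts(r, "verification_counts r")
  u <- check_counts(u, "verification_counts u")
  if (length(s) != length(r) || length(s) != length(u))
    stop("verification_counts: s, r, u must have equal length", call. = FALSE)
  m <- s + r + u
  if (sum(m) == 0) stop("verification_counts: total count must be positive", call. = FALSE)
  structure(list(k = length(s), s = s, r = r, u = u, m = m),
            class = "verification_counts")
}

#' @export
print.verification_counts <- function(x, ...) {
  cat("Verification study,", x$k, "result categories, n =", sum(x$m), "\n")
  print(rbind("verified D=1 (s)" = x$s, "verified D=0 (r)" = x$r,
              "unverified (u)" = x$u, "total (m)" = x$m))
  invisible(x)
}

#' Cross-tabulation of a reference test and a new test, no gold standard
#'
#' Counts `n[R, T]` of reference-by-new-test outcomes with no disease
#' labels.  Rows index the reference result R (0 then 1), columns the new
#' test T.  The first index is R because in the conditional-independence
#' likelihood the new test's sensitivity pairs with the T = 1 column
#' (cells (R=1,T=1) and (R=0,T=1)).
#'
#' @param n A 2x2 matrix of counts, rows R = 0,1, columns T = 0,1.
#' @return An object of class `nogold_crosstab`.
#' @export
nogold_crosstab <- function(n) {
  n <- matrix(check_counts(n, "nogold_crosstab"), 2, 2,
              dimnames = list(c("R=0", "R=1"), c("T=0", "T=1")))
  if (sum(n) == 0) stop("nogold_crosstab: total count must be positive", call. = FALSE)
  structure(list(counts = n), class = "nogold_crosstab")
}

#' @export
print.nogold_crosstab <- function(x, ...) {
  cat("Reference-by-new-test cross-tab, no gold standard (n =", sum(x$counts), ")\n")
  print(x$counts)
  invisible(x)
}

#' Subject-level test scores with binary disease labels
#'
#' @param values Numeric test scores (continuous or ordinal), all finite.
#' @param labels Disease indicators, 0 = non-diseased, 1 = diseased; at
#'   least one subject per label.
#' @return An object of class `score_set`.
#' @export
score_set <- function(values, labels) {
  if (length(values) != length(labels))
    stop("score_set: values and labels must have equal length", call. = FALSE)
  if (!all(is.finite(values)))
    stop("score_set: scores must be finite", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("score_set: labels must be 0 or 1", call. = FALSE)
  if (!any(labels == 0) || !any(labels == 1))
    stop("score_set: need at least one subject per disease label", call. = FALSE)
  structure(list(values = as.numeric(values), labels = as.integer(labels)),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("Score set: ", sum(x$labels == 1), " diseased, ",
      sum(x$labels == 0), " non-diseased subjects\n", sep = "")
  invisible(x)
}
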