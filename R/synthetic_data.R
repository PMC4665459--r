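# Generators that produce datasets with the exact statistical structure
# each estimator assumes, for parameter-recovery and coverage testing.
# Every generator is deterministic under a fixed seed and emits the same
# containers (hence the same file formats) the readers consume.

#' Simulate a 2x2 table for one binary test with a gold standard
#'
#' Disease status is Bernoulli(`prevalence`); the test result given
#' disease follows (`tpf`, `fpf`).
#'
#' @param n Number of subjects.
#' @param prevalence,tpf,fpf Generating probabilities.
#' @param seed Integer seed.
#' @return A `count_table_2x2`.
#' @export
gen_binary <- function(n, prevalence, tpf, fpf, seed = 1) {
  check_prob(c(prevalence = prevalence, tpf = tpf, fpf = fpf))
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(n, 1, prevalence)
  x <- stats::rbinom(n, 1, ifelse(d == 1, tpf, fpf))
  count_table_2x2(sum(x == 0 & d == 0), sum(x == 0 & d == 1),
                  sum(x == 1 & d == 0), sum(x == 1 & d == 1))
}

check_prob <- function(p, simplex = FALSE) {
  if (any(p < 0) || any(p > 1))
    stop("generator: probabilities must lie in [0,1] (",
         paste(names(p), collapse = ", "), ")", call. = FALSE)
  if (simplex && abs(sum(p) - 1) > 1e-8)
    stop("generator: probabilities must sum to 1", call. = FALSE)
  invisible(p)
}

#' Simulate a verification-bias study under MAR
#'
#' Generates (Y, D) from the category distributions, then verifies each
#' subject with a probability depending only on the observed result Y
#' (the missing-at-random mechanism); unverified subjects contribute to
#' the `u` margin.
#'
#' @param n Number of subjects.
#' @param prevalence Disease rate.
#' @param cat_diseased,cat_nondiseased Length-k probability vectors of
#'   the result category given disease / no disease.  For a binary test
#'   use `c(1 - tpf, tpf)` and `c(1 - fpf, fpf)`.
#' @param verify_prob Length-k vector of verification probabilities per
#'   result category.
#' @param seed Integer seed.
#' @return A `verification_counts`.
#' @export
gen_verified <- function(n, prevalence, cat_diseased, cat_nondiseased,
                         verify_prob, seed = 1) {
  k <- length(cat_diseased)
  stopifnot(length(cat_nondiseased) == k, length(verify_prob) == k, n >= 1)
  check_prob(c(prevalence = prevalence))
  check_prob(cat_diseased, simplex = TRUE)
  check_prob(cat_nondiseased, simplex = TRUE)
  check_prob(verify_prob)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(n, 1, prevalence)
  ycat <- integer(n)
  if (any(d == 1)) ycat[d == 1] <- sample.int(k, sum(d), TRUE, cat_diseased)
  if (any(d == 0)) ycat[d == 0] <- sample.int(k, sum(d == 0), TRUE, cat_nondiseased)
  v <- stats::rbinom(n, 1, verify_prob[ycat])
  tab <- function(cond) tabulate(ycat[cond], nbins = k)
  verification_counts(s = tab(v == 1 & d == 1),
                      r = tab(v == 1 & d == 0),
                      u = tab(v == 0))
}

#' Simulate two conditionally independent tests with no gold standard
#'
#' Disease status D is latent Bernoulli(`p`); given D the reference R and
#' new test T are independent with accuracies (s2, c2) and (s1, c1).
#' Only the R-by-T cross-tab is returned.
#'
#' @param n Number of subjects.
#' @param p Prevalence.
#' @param s1,c1 Sensitivity and specificity of the new test T.
#' @param s2,c2 Sensitivity and specificity of the reference R.
#' @param seed Integer seed.
#' @return A `nogold_crosstab`.
#' @export
gen_no_gold <- function(n, p, s1, c1, s2, c2, seed = 1) {
  check_prob(c(p = p, s1 = s1, c1 = c1, s2 = s2, c2 = c2))
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(n, 1, p)
  t <- stats::rbinom(n, 1, ifelse(d == 1, s1, 1 - c1))
  r <- stats::rbinom(n, 1, ifelse(d == 1, s2, 1 - c2))
  nogold_crosstab(matrix(c(sum(r == 0 & t == 0), sum(r == 0 & t == 1),
                           sum(r == 1 & t == 0), sum(r == 1 & t == 1)),
                         2, 2, byrow = TRUE))
}

#' Simulate paired binary tests from joint cell probabilities
#'
#' @param n_diseased,n_nondiseased Group sizes.
#' @param theta,phi 2x2 matrices of joint (test1, test2) cell
#'   probabilities for the diseased / non-diseased groups, each summing
#'   to 1.
#' @param seed Integer seed.
#' @return A `paired_binary_counts`.
#' @export
gen_paired_binary <- function(n_diseased, n_nondiseased, theta, phi, seed = 1) {
  check_prob(as.vector(theta), simplex = TRUE)
  check_prob(as.vector(phi), simplex = TRUE)
  stopifnot(n_diseased >= 1, n_nondiseased >= 1)
  if (!is.null(seed)) set.seed(seed)
  cd <- stats::rmultinom(1, n_diseased, as.vector(t(theta)))
  cn <- stats::rmultinom(1, n_nondiseased, as.vector(t(phi)))
  paired_binary_counts(matrix(cd, 2, 2, byrow = TRUE),
                       matrix(cn, 2, 2, byrow = TRUE))
}

#' Simulate ordinal counts from category probabilities
#'
#' @param n_diseased,n_nondiseased Group sizes.
#' @param theta,phi Length-k category probability vectors for the
#'   diseased / non-diseased scores.
#' @param seed Integer seed.
#' @return An `ordinal_counts`.
#' @export
gen_ordinal <- function(n_diseased, n_nondiseased, theta, phi, seed = 1) {
  check_prob(theta, simplex = TRUE); check_prob(phi, simplex = TRUE)
  if (!is.null(seed)) set.seed(seed)
  ordinal_counts(drop(stats::rmultinom(1, n_diseased, theta)),
                 drop(stats::rmultinom(1, n_nondiseased, phi)))
}

#' Simulate a paired ordinal joint table
#'
#' @param n_diseased,n_nondiseased Group sizes.
#' @param theta,phi k x k joint cell probability matrices (rows = test1
#'   score, columns = test2 score), each summing to 1.
#' @param seed Integer seed.
#' @return A list with k x k count matrices `diseased`, `nondiseased`.
#' @export
gen_ordinal_joint <- function(n_diseased, n_nondiseased, theta, phi, seed = 1) {
  theta <- as.matrix(theta); phi <- as.matrix(phi)
  check_prob(as.vector(theta), simplex = TRUE)
  check_prob(as.vector(phi), simplex = TRUE)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(theta)
  list(diseased = matrix(stats::rmultinom(1, n_diseased, as.vector(theta)), k, k),
       nondiseased = matrix(stats::rmultinom(1, n_nondiseased, as.vector(phi)), k, k))
}

#' Simulate continuous binormal scores
#'
#' @param n_diseased,n_nondiseased Group sizes.
#' @param mu_d,sd_d Mean and standard deviation of the diseased scores.
#' @param mu_nd,sd_nd Mean and standard deviation of the non-diseased
#'   scores.
#' @param seed Integer seed.
#' @return A `score_set` with the diseased subjects first.
#' @export
gen_scores <- function(n_diseased, n_nondiseased, mu_d, sd_d, mu_nd, sd_nd,
                       seed = 1) {
  stopifnot(n_diseased >= 1, n_nondiseased >= 1, sd_d > 0, sd_nd > 0)
  if (!is.null(seed)) set.seed(seed)
  score_set(c(stats::rnorm(n_diseased, mu_d, sd_d),
              stats::rnorm(n_nondiseased, mu_nd, sd_nd)),
            c(rep(1, n_diseased), rep(0, n_nondiseased)))
}

#' Simulate subject-level records from a logistic risk model
#'
#' Test scores are drawn uniformly over a discrete grid and disease
#' status from `plogis(b1 + b2*T1 + b3*T2 + ...)`.
#'
#' @param n Number of subjects.
#' @param coefs Coefficient vector, intercept first.
#' @param levels Score levels each test is sampled from (uniformly).
#' @param seed Integer seed.
#' @return A data frame with predictor columns `T1`, `T2`, ... and a 0/1
#'   column `d`, suitable for [fit_risk_score()].
#' @export
gen_logistic_subjects <- function(n, coefs, levels = 1:5, seed = 1) {
  stopifnot(n >= 1, length(coefs) >= 2)
  if (!is.null(seed)) set.seed(seed)
  p <- length(coefs) - 1
  tests <- matrix(sample(levels, n * p, TRUE), n, p,
                  dimnames = list(NULL, paste0("T", seq_len(p))))
  eta <- coefs[1] + drop(tests %*% coefs[-1])
  out <- as.data.frame(tests)
  out$d <- stats::rbinom(n, 1, stats::plogis(eta))
  out
}
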