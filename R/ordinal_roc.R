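# Empirical ROC points and Bayesian AUC for ordinal-score tests.
#
# With P(Y = i) = theta_i for the diseased score and P(X = j) = phi_j for
# the non-diseased score, the area under the linearly interpolated ROC is
#   AUC = P(Y > X) + P(Y = X) / 2
#       = sum_{i > j} theta_i phi_j + (1/2) sum_i theta_i phi_i.

#' Empirical ROC points for ordinal counts
#'
#' For each category threshold c the test is called positive when the
#' score is >= c; tpf(c) and fpf(c) are the corresponding cumulative
#' fractions.  The degenerate endpoints (1,1) (threshold below the scale)
#' and (0,0) (threshold above it) are included, so the points are ready
#' for trapezoid computations.
#'
#' @param counts An `ordinal_counts`.
#' @return A data frame with columns `threshold`, `fpf`, `tpf`, ordered by
#'   increasing threshold; `fpf` and `tpf` are non-increasing.
#' @examples
#' empirical_roc_points(load_fixture("mammogram"))
#' @export
empirical_roc_points <- function(counts) {
  stopifnot(inherits(counts, "ordinal_counts"))
  nd <- sum(counts$diseased)
  nn <- sum(counts$nondiseased)
  if (nd == 0 || nn == 0)
    stop("empirical_roc_points: each group needs a positive total", call. = FALSE)
  k <- counts$k
  tpf <- rev(cumsum(rev(counts$diseased))) / nd
  fpf <- rev(cumsum(rev(counts$nondiseased))) / nn
  data.frame(threshold = c(1:k, k + 1),
             fpf = c(fpf, 0), tpf = c(tpf, 0))
}

#' Posterior of the ordinal ROC area
#'
#' Independent uniform-prior Dirichlet posteriors are placed on the
#' diseased category probabilities theta and the non-diseased phi; per
#' draw the area is `A1 + A2/2` with `A1 = P(Y > X)` and `A2 = P(Y = X)`.
#'
#' @param counts An `ordinal_counts`.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `dta_auc` fit with summaries `auc`, `A1`, `A2`.
#' @export
auc_ordinal_posterior <- function(counts, n_draws = 55000, seed = 1) {
  stopifnot(inherits(counts, "ordinal_counts"))
  post_t <- dirichlet_posterior(counts$diseased)
  post_p <- dirichlet_posterior(counts$nondiseased)
  th <- draw(post_t, n_draws, seed)
  ph <- draw(post_p, n_draws, seed = NULL)
  k <- counts$k
  # P(X < i) per draw: cumulative phi strictly below category i
  ph_cum <- cbind(0, t(apply(ph, 1, cumsum)))[, 1:k, drop = FALSE]
  a1 <- rowSums(th * ph_cum)
  a2 <- rowSums(th * ph)
  draws <- cbind(auc = a1 + a2 / 2, A1 = a1, A2 = a2)
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("dta_auc", "Posterior ROC area for ordinal scores",
              sums, draws,
              list(posterior_diseased = post_t, posterior_nondiseased = post_p,
                   seed = seed, counts = counts))
}

#' Exact posterior mean of the ordinal ROC area
#'
#' The area is bilinear in (theta, phi) and the two posteriors are
#' independent, so its posterior mean equals the area evaluated at the
#' posterior means.  Used as the closed-form oracle for
#' `auc_ordinal_posterior()`.
#'
#' @param theta_posterior,phi_posterior `dirichlet_posterior` objects of
#'   equal dimension for the diseased and non-diseased category
#'   probabilities.
#' @return The exact expected AUC.
#' @export
auc_ordinal_expectation <- function(theta_posterior, phi_posterior) {
  stopifnot(inherits(theta_posterior, "dirichlet_posterior"),
            inherits(phi_posterior, "dirichlet_posterior"))
  if (length(theta_posterior$alpha) != length(phi_posterior$alpha))
    stop("auc_ordinal_expectation: dimension mismatch", call. = FALSE)
  th <- theta_posterior$alpha / sum(theta_posterior$alpha)
  ph <- phi_posterior$alpha / sum(phi_posterior$alpha)
  k <- length(th)
  below <- c(0, cumsum(ph))[1:k]
  sum(th * below) + sum(th * ph) / 2
}
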