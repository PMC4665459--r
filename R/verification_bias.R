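# Bias-corrected accuracy under missing-at-random (MAR) verification.
#
# Parameterise by phi_i = P(D=1 | Y=i) (disease given result) and
# theta_i = P(Y=i) (result margin).  Under MAR -- verification depends on
# the test result only, P(V=1 | D, Y) = P(V=1 | Y) -- the likelihood
# factorises so that, with uniform priors,
#   phi_i ~ Beta(s_i + 1, r_i + 1)  independently, and
#   theta ~ Dirichlet(m_1 + 1, ..., m_k + 1),
# and Bayes' theorem converts draws of (phi, theta) into the
# result-given-disease fractions alpha_i = P(Y=i | D=1) and
# beta_i = P(Y=i | D=0).

#' Naive accuracy estimates from the verified subjects only
#'
#' Point estimates of sensitivity and FPF computed as if the verified
#' subset were a complete study.  When positives are verified
#' preferentially these overstate both fractions; they are the foil for
#' `corrected_binary()`.
#'
#' @param v A `verification_counts` with `k = 2` (category 2 = positive).
#' @return A list with `sensitivity` and `fpf`.
#' @examples
#' naive_estimates(load_fixture("scintigraphy"))  # 298/329 and 26/74
#' @export
naive_estimates <- function(v) {
  stopifnot(inherits(v, "verification_counts"))
  if (v$k != 2) stop("naive_estimates: binary test required (k = 2)", call. = FALSE)
  if (sum(v$s) == 0 || sum(v$r) == 0)
    stop("naive_estimates: need verified subjects in both disease classes", call. = FALSE)
  list(sensitivity = v$s[2] / sum(v$s), fpf = v$r[2] / sum(v$r))
}

# draw (phi matrix, theta matrix) from the verification posteriors
draw_verification <- function(v, n_draws, seed) {
  if (!is.null(seed)) set.seed(seed)
  k <- v$k
  phi <- sapply(seq_len(k), function(i)
    stats::rbeta(n_draws, v$s[i] + 1, v$r[i] + 1))
  theta <- rdirichlet(n_draws, v$m + 1)
  list(phi = phi, theta = theta)
}

#' Verification-bias-corrected TPF and FPF for a binary test
#'
#' Per i.i.d. draw of (phi, theta) computes the corrected sensitivity
#' `alpha1 = phi1*theta1 / P(D=1)` and false positive fraction
#' `beta1 = (1-phi1)*theta1 / P(D=0)` with `P(D=1) = sum_i phi_i theta_i`,
#' where subscript 1 denotes the positive result.
#'
#' @param v A `verification_counts` with `k = 2`.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `dta_verification` fit with summaries `tpf`, `fpf`,
#'   `prevalence`.
#' @export
corrected_binary <- function(v, n_draws = 50000, seed = 1) {
  stopifnot(inherits(v, "verification_counts"))
  if (v$k != 2) stop("corrected_binary: binary test required (k = 2)", call. = FALSE)
  dv <- draw_verification(v, n_draws, seed)
  pd <- rowSums(dv$phi * dv$theta)            # P(D=1) per draw
  tpf <- dv$phi[, 2] * dv$theta[, 2] / pd
  fpf <- (1 - dv$phi[, 2]) * dv$theta[, 2] / (1 - pd)
  draws <- cbind(tpf = tpf, fpf = fpf, prevalence = pd)
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("dta_verification", "Verification-bias-corrected accuracy (MAR)",
              sums, draws, list(seed = seed, counts = v))
}

#' Verification-bias-corrected ROC area for an ordinal test
#'
#' Per draw converts (phi, theta) into the result-given-disease fractions
#' alpha_i and beta_i by Bayes' theorem and computes the ordinal ROC area
#' `A = A1 + A2_raw/2` with `A1 = sum_{i>=2} alpha_i * sum_{j<i} beta_j`
#' and the tie probability `A2_raw = sum_i alpha_i beta_i`.
#'
#' The reported `A2` row is the *halved* tie term `A2_raw / 2`, so the
#' table satisfies `A = A1 + A2` directly (the convention of the study
#' this estimator reproduces); the un-halved tie probability is kept as
#' `tie_prob`.
#'
#' @param v A `verification_counts`, `k >= 2`.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `dta_verification_auc` fit with summaries `A`, `A1`, `A2`
#'   (= tie/2), `tie_prob` and `prevalence`.
#' @export
corrected_ordinal_auc <- function(v, n_draws = 55000, seed = 1) {
  stopifnot(inherits(v, "verification_counts"))
  dv <- draw_verification(v, n_draws, seed)
  k <- v$k
  pt <- dv$phi * dv$theta
  pd <- rowSums(pt)
  alpha <- pt / pd
  beta <- (1 - dv$phi) * dv$theta / (1 - pd)
  beta_below <- cbind(0, t(apply(beta, 1, cumsum)))[, 1:k, drop = FALSE]
  a1 <- rowSums(alpha * beta_below)
  tie <- rowSums(alpha * beta)
  draws <- cbind(A = a1 + tie / 2, A1 = a1, A2 = tie / 2,
                 tie_prob = tie, prevalence = pd)
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("dta_verification_auc",
              "Verification-bias-corrected ordinal ROC area (MAR)",
              sums, draws,
              list(alpha_draws = alpha, beta_draws = beta,
                   seed = seed, counts = v))
}
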