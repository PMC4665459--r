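# Latent-class Gibbs sampler for two conditionally independent binary
# tests with no gold standard.
#
# Observed: the 2x2 cross-tab n[R, T] of a reference test R and a new
# test T.  Latent: the number y[R, T] of truly diseased subjects in each
# cell.  Parameters: disease prevalence p, the new test's sensitivity s1
# and specificity c1, and the reference's s2 and c2.  Given the latent
# counts every parameter has a conjugate Beta full conditional; given the
# parameters each y[R, T] is Binomial with the cell's posterior
# probability of disease.

#' Beta prior hyperparameters for the latent-class model
#'
#' @param p,s1,s2,c1,c2 Length-2 vectors `c(alpha, beta)` of positive
#'   Beta hyperparameters for the prevalence, new-test sensitivity,
#'   reference sensitivity, new-test specificity and reference
#'   specificity.  Defaults are uniform.
#' @return A list of class `lc_priors`.
#' @export
lc_priors <- function(p = c(1, 1), s1 = c(1, 1), s2 = c(1, 1),
                      c1 = c(1, 1), c2 = c(1, 1)) {
  pri <- list(p = p, s1 = s1, s2 = s2, c1 = c1, c2 = c2)
  for (nm in names(pri)) {
    h <- pri[[nm]]
    if (length(h) != 2 || !is.numeric(h) || any(h <= 0))
      stop("lc_priors: ", nm, " must be two positive hyperparameters", call. = FALSE)
  }
  structure(pri, class = "lc_priors")
}

#' Per-cell probability that a subject is diseased
#'
#' For a subject in cell (R = i, T = j), the conditional probability of
#' disease given the parameters, e.g. for the both-positive cell
#' `m11 = p*s1*s2 / (p*s1*s2 + (1-p)*(1-c1)*(1-c2))`.
#'
#' @param p,s1,s2,c1,c2 Probabilities in (0, 1): prevalence, new-test
#'   sensitivity/specificity (s1/c1), reference sensitivity/specificity
#'   (s2/c2).
#' @return Named vector `m11, m10, m01, m00` indexed (R, T).
#' @export
cell_assignment_probs <- function(p, s1, s2, c1, c2) {
  args <- c(p = p, s1 = s1, s2 = s2, c1 = c1, c2 = c2)
  if (any(args <= 0) || any(args >= 1))
    stop("cell_assignment_probs: all arguments must lie strictly in (0,1)",
         call. = FALSE)
  m <- function(sd, snd) {
    den <- p * sd + (1 - p) * snd
    if (den == 0) stop("cell_assignment_probs: degenerate 0/0 cell", call. = FALSE)
    p * sd / den
  }
  c(m11 = m(s1 * s2, (1 - c1) * (1 - c2)),
    m10 = m((1 - s1) * s2, c1 * (1 - c2)),
    m01 = m(s1 * (1 - s2), (1 - c1) * c2),
    m00 = m((1 - s1) * (1 - s2), c1 * c2))
}

#' Gibbs sampler for two binary tests without a gold standard
#'
#' Alternates (i) sampling the latent diseased count of each cell from
#' its Binomial conditional via `cell_assignment_probs()`, and
#' (ii) sampling p, s1, s2, c1, c2 from their conjugate Beta
#' conditionals, with informative priors entering by adding the prior
#' hyperparameters to the latent success/failure counts.
#'
#' With uniform priors the likelihood is invariant under the relabelling
#' (p, s, c) -> (1-p, 1-c, 1-s), so the posterior is bimodal and the
#' parameters are only weakly identified; informative priors on the
#' accuracies resolve the ambiguity.
#'
#' @param counts A `nogold_crosstab`.
#' @param priors An `lc_priors`; uniform by default.
#' @param n_iter Total Gibbs iterations.
#' @param burnin Iterations discarded.
#' @param seed Integer seed.
#' @return A `latent_class_fit` with summaries for `p`, `s1`, `s2`, `c1`,
#'   `c2` and the retained draws.
#' @export
gibbs_no_gold <- function(counts, priors = lc_priors(), n_iter = 125000,
                          burnin = 10000, seed = 1) {
  stopifnot(inherits(counts, "nogold_crosstab"), inherits(priors, "lc_priors"))
  if (n_iter <= burnin || burnin < 0)
    stop("gibbs_no_gold: need n_iter > burnin >= 0", call. = FALSE)
  n <- counts$counts
  n11 <- n["R=1", "T=1"]; n10 <- n["R=1", "T=0"]
  n01 <- n["R=0", "T=1"]; n00 <- n["R=0", "T=0"]
  ntot <- sum(n)
  if (!is.null(seed)) set.seed(seed)
  pm <- function(h) h[1] / (h[1] + h[2])     # prior mean as initial value
  p <- pm(priors$p); s1 <- pm(priors$s1); s2 <- pm(priors$s2)
  c1 <- pm(priors$c1); c2 <- pm(priors$c2)
  clamp <- function(x) min(max(x, 1e-12), 1 - 1e-12)
  keep <- n_iter - burnin
  out <- matrix(NA_real_, keep, 5,
                dimnames = list(NULL, c("p", "s1", "s2", "c1", "c2")))
  for (it in seq_len(n_iter)) {
    m <- cell_assignment_probs(clamp(p), clamp(s1), clamp(s2),
                               clamp(c1), clamp(c2))
    y11 <- stats::rbinom(1, n11, m["m11"])
    y10 <- stats::rbinom(1, n10, m["m10"])
    y01 <- stats::rbinom(1, n01, m["m01"])
    y00 <- stats::rbinom(1, n00, m["m00"])
    ysum <- y11 + y10 + y01 + y00
    p  <- stats::rbeta(1, ysum + priors$p[1], ntot - ysum + priors$p[2])
    s1 <- stats::rbeta(1, y11 + y01 + priors$s1[1], y10 + y00 + priors$s1[2])
    s2 <- stats::rbeta(1, y11 + y10 + priors$s2[1], y01 + y00 + priors$s2[2])
    c1 <- stats::rbeta(1, n10 + n00 - y10 - y00 + priors$c1[1],
                          n11 + n01 - y11 - y01 + priors$c1[2])
    c2 <- stats::rbeta(1, n01 + n00 - y01 - y00 + priors$c2[1],
                          n11 + n10 - y11 - y10 + priors$c2[2])
    if (it > burnin) out[it - burnin, ] <- c(p, s1, s2, c1, c2)
  }
  sums <- lapply(colnames(out), function(par) summarize_draws(out[, par], par))
  names(sums) <- colnames(out)
  new_dta_fit("latent_class_fit",
              "Latent-class model for two tests without a gold standard",
              sums, out,
              list(seed = seed, n_iter = n_iter, burnin = burnin,
                   priors = priors, counts = counts))
}

#' Apparent accuracy of the new test relative to the reference
#'
#' Treats the (imperfect) reference as if it were a gold standard:
#' apparent sensitivity `n[R=1,T=1] / n[R=1,.]` and apparent specificity
#' `n[R=0,T=0] / n[R=0,.]`.  These are generally biased for the true
#' accuracies; compare with `gibbs_no_gold()`.
#'
#' @param counts A `nogold_crosstab` with positive reference margins.
#' @return A list with `sensitivity` and `specificity`.
#' @export
observed_vs_reference <- function(counts) {
  stopifnot(inherits(counts, "nogold_crosstab"))
  n <- counts$counts
  pos <- sum(n["R=1", ]); neg <- sum(n["R=0", ])
  if (pos == 0 || neg == 0)
    stop("observed_vs_reference: empty reference stratum", call. = FALSE)
  list(sensitivity = n["R=1", "T=1"] / pos,
       specificity = n["R=0", "T=0"] / neg)
}
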