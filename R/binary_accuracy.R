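# Posterior inference for the basic accuracy measures of one binary test
# and paired comparison of two binary modalities.
#
# With a uniform prior the cell probabilities of the 2x2 table are
# Dirichlet(n00+1, n01+1, n10+1, n11+1) a posteriori; every measure is a
# function of the cell probabilities, so its posterior is obtained by
# transforming Dirichlet draws.

# cells are ordered (00, 01, 10, 11) throughout
CELL00 <- 1L; CELL01 <- 2L; CELL10 <- 3L; CELL11 <- 4L

#' Posterior accuracy measures for one binary test
#'
#' Draws from the uniform-prior Dirichlet posterior of the 2x2 cell
#' probabilities and summarises the transformed draws of:
#' TPF = P(X=1|D=1) (sensitivity), FPF = P(X=1|D=0), PPV = P(D=1|X=1),
#' NPV = P(D=0|X=0), the diagnostic likelihood ratios PDLR = TPF/FPF and
#' NDLR = FNF/TNF, and the complements FNF = 1-TPF, TNF = 1-FPF.
#'
#' Note on PPV: the predictive values condition on the *test* margin, so
#' PPV = theta11/(theta10 + theta11) and NPV = theta00/(theta00 + theta01).
#'
#' @param table A `count_table_2x2`.
#' @param n_draws Monte Carlo sample size (i.i.d. conjugate draws).
#' @param seed Integer seed.
#' @param prior Dirichlet prior concentrations, uniform by default.
#' @return An object of class `dta_accuracy` (a `dta_fit`): posterior
#'   `summary` table, raw `draws` matrix, and the `posterior` used.
#' @examples
#' fit <- basic_measures(load_fixture("est_cad"), n_draws = 5000, seed = 1)
#' summary(fit)
#' @export
basic_measures <- function(table, n_draws = 55000, seed = 1,
                           prior = rep(1, 4)) {
  stopifnot(inherits(table, "count_table_2x2"))
  post <- dirichlet_posterior(as.vector(t(table$counts)), prior)
  th <- draw(post, n_draws, seed)
  eps <- .Machine$double.xmin
  floored <- FALSE
  rat <- function(num, den) {
    if (any(den <= 0)) floored <<- TRUE
    num / pmax(den, eps)
  }
  tpf <- rat(th[, CELL11], th[, CELL11] + th[, CELL01])
  fpf <- rat(th[, CELL10], th[, CELL00] + th[, CELL10])
  ppv <- rat(th[, CELL11], th[, CELL10] + th[, CELL11])
  npv <- rat(th[, CELL00], th[, CELL00] + th[, CELL01])
  fnf <- 1 - tpf
  tnf <- 1 - fpf
  draws <- cbind(TPF = tpf, FPF = fpf, PPV = ppv, NPV = npv,
                 PDLR = rat(tpf, fpf), NDLR = rat(fnf, tnf),
                 FNF = fnf, TNF = tnf)
  if (floored)
    warning("basic_measures: a zero denominator was floored (should not occur ",
            "under Dirichlet draws)")
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("dta_accuracy", "Posterior accuracy measures for a binary test",
              sums, draws,
              list(posterior = post, cell_draws = th, seed = seed,
                   table = table))
}

#' Paired comparison of two binary tests
#'
#' Independent uniform-prior Dirichlet posteriors are placed on the
#' (test1, test2) cell probabilities of the diseased and of the
#' non-diseased subjects.  Per draw, each test's TPF is its
#' positive-margin sum among the diseased cells and its FPF the analogue
#' among non-diseased cells; the ratios TPF1/TPF2 and FPF1/FPF2 are
#' summarised per draw (the mean of the ratio, not the ratio of means).
#'
#' @param tables A `paired_binary_counts`.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `dta_paired` fit with summaries `tpf1`, `tpf2`, `fpf1`,
#'   `fpf2`, `rtpf` (= TPF1/TPF2), `rfpf` (= FPF1/FPF2).
#' @export
compare_paired <- function(tables, n_draws = 55000, seed = 1) {
  stopifnot(inherits(tables, "paired_binary_counts"))
  post_d <- dirichlet_posterior(as.vector(t(tables$diseased)))
  post_n <- dirichlet_posterior(as.vector(t(tables$nondiseased)))
  th <- draw(post_d, n_draws, seed)
  ph <- draw(post_n, n_draws, seed = NULL)
  tpf1 <- th[, CELL10] + th[, CELL11]   # test1 positive margin, diseased
  tpf2 <- th[, CELL01] + th[, CELL11]
  fpf1 <- ph[, CELL10] + ph[, CELL11]
  fpf2 <- ph[, CELL01] + ph[, CELL11]
  draws <- cbind(tpf1 = tpf1, tpf2 = tpf2, fpf1 = fpf1, fpf2 = fpf2,
                 rtpf = tpf1 / tpf2, rfpf = fpf1 / fpf2)
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("dta_paired", "Paired comparison of two binary tests",
              sums, draws,
              list(posterior_diseased = post_d, posterior_nondiseased = post_n,
                   seed = seed, tables = tables))
}
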