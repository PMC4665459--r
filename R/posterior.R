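# Conjugate posterior construction, sampling and summaries shared by all
# model modules.

#' Dirichlet posterior for multinomial cell counts
#'
#' Under a Dirichlet prior (uniform by default) the posterior of the cell
#' probabilities is Dirichlet with concentration `counts + prior`.
#'
#' @param counts Non-negative integer counts.
#' @param prior Positive concentration parameters of the Dirichlet prior;
#'   defaults to all ones (the uniform prior on the simplex).
#' @return An object of class `dirichlet_posterior` with field `alpha`.
#' @examples
#' dirichlet_posterior(c(327, 208, 115, 818))
#' @export
dirichlet_posterior <- function(counts, prior = rep(1, length(counts))) {
  counts <- check_counts(counts, "dirichlet_posterior")
  if (length(prior) != length(counts))
    stop("dirichlet_posterior: prior and counts must have equal length", call. = FALSE)
  if (!is.numeric(prior) || any(prior <= 0))
    stop("dirichlet_posterior: prior concentrations must be positive", call. = FALSE)
  structure(list(alpha = counts + prior), class = "dirichlet_posterior")
}

#' @export
print.dirichlet_posterior <- function(x, ...) {
  cat("Dirichlet(", paste(format(x$alpha), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Beta posterior
#'
#' @param a,b Positive shape parameters.
#' @return An object of class `beta_posterior`.
#' @export
beta_posterior <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop("beta_posterior: shapes must be positive", call. = FALSE)
  structure(list(a = a, b = b), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat("Beta(", format(x$a), ", ", format(x$b), "), mean ",
      format(x$a / (x$a + x$b), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Draw Monte Carlo samples from a conjugate posterior
#'
#' Sampling is i.i.d. (no Markov chain is needed for the conjugate
#' families), so no burn-in applies.  The same seed gives bit-identical
#' draws.
#'
#' @param posterior A `dirichlet_posterior` or `beta_posterior`.
#' @param n_draws Number of samples, at least 1.  The default 55000
#'   matches the run length used throughout the worked examples.
#' @param seed Integer seed; `NULL` leaves the random stream untouched.
#' @return For a Dirichlet, an `n_draws` x m matrix whose rows sum to 1;
#'   for a Beta, a vector in (0, 1).
#' @export
draw <- function(posterior, n_draws = 55000, seed = NULL) {
  if (!is.numeric(n_draws) || n_draws < 1)
    stop("draw: n_draws must be at least 1", call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)
  UseMethod("draw")
}

#' @export
draw.dirichlet_posterior <- function(posterior, n_draws = 55000, seed = NULL) {
  rdirichlet(n_draws, posterior$alpha)
}

#' @export
draw.beta_posterior <- function(posterior, n_draws = 55000, seed = NULL) {
  stats::rbeta(n_draws, posterior$a, posterior$b)
}

# Gamma-ratio construction of Dirichlet variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Summarise posterior draws
#'
#' Mean, standard deviation, Monte Carlo standard error and the 2.5%, 50%
#' and 97.5% empirical quantiles, mirroring the layout of a standard
#' Bayesian output table.  The Monte Carlo error is estimated by batch
#' means with 50 batches.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param name Optional parameter name attached to the summary.
#' @return An object of class `posterior_summary`: a named list with
#'   fields `mean`, `sd`, `mc_error`, `q025`, `median`, `q975`, `n_draws`.
#' @export
summarize_draws <- function(draws, name = NULL) {
  if (!is.numeric(draws) || length(draws) < 100)
    stop("summarize_draws: need at least 100 draws", call. = FALSE)
  q <- unname(stats::quantile(draws, c(0.025, 0.5, 0.975), type = 7))
  structure(list(name = name,
                 mean = mean(draws), sd = stats::sd(draws),
                 mc_error = batch_means_se(draws),
                 q025 = q[1], median = q[2], q975 = q[3],
                 n_draws = length(draws)),
            class = "posterior_summary")
}

# Batch-means Monte Carlo standard error with 50 batches; draws beyond a
# multiple of the batch size are dropped.
batch_means_se <- function(draws, n_batches = 50) {
  b <- length(draws) %/% n_batches
  if (b < 1) return(stats::sd(draws) / sqrt(length(draws)))
  m <- matrix(draws[seq_len(b * n_batches)], nrow = b)
  stats::sd(colMeans(m)) / sqrt(n_batches)
}

#' @export
print.posterior_summary <- function(x, ...) {
  print(as.data.frame(posterior_table(list(x))), digits = 4)
  invisible(x)
}

#' Collect posterior summaries into a result table
#'
#' @param summaries A named list of `posterior_summary` objects (names
#'   override the summaries' own names if given).
#' @return A data frame of class `posterior_table` with one row per
#'   parameter and columns `mean`, `sd`, `mc_error`, `q025`, `median`,
#'   `q975`.
#' @export
posterior_table <- function(summaries) {
  nms <- names(summaries)
  if (is.null(nms)) nms <- vapply(summaries, function(s) s$name %||% "", "")
  out <- data.frame(
    parameter = nms,
    mean = vapply(summaries, `[[`, 0, "mean"),
    sd = vapply(summaries, `[[`, 0, "sd"),
    mc_error = vapply(summaries, `[[`, 0, "mc_error"),
    q025 = vapply(summaries, `[[`, 0, "q025"),
    median = vapply(summaries, `[[`, 0, "median"),
    q975 = vapply(summaries, `[[`, 0, "q975"),
    row.names = NULL)
  class(out) <- c("posterior_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_table <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Exact Beta distribution of a Dirichlet sub-sum ratio
#'
#' If `theta ~ Dirichlet(alpha)` and `N` is a subset of a denominator
#' index set `D`, then `sum(theta[N]) / sum(theta[D])` is distributed
#' `Beta(sum(alpha[N]), sum(alpha[D \ N]))` by the aggregation property of
#' the Dirichlet.  This gives closed-form means for every accuracy
#' measure expressible as a sub-sum ratio (sensitivity, specificity,
#' predictive values), and serves as the exact oracle for the Monte Carlo
#' routines.
#'
#' @param posterior A `dirichlet_posterior`.
#' @param numerator,denominator Integer index sets with
#'   `numerator` strictly contained in `denominator`.
#' @return A `beta_posterior`.
#' @examples
#' post <- dirichlet_posterior(c(327, 208, 115, 818))
#' beta_margin(post, numerator = 4, denominator = c(2, 4))  # sensitivity
#' @export
beta_margin <- function(posterior, numerator, denominator) {
  stopifnot(inherits(posterior, "dirichlet_posterior"))
  m <- length(posterior$alpha)
  if (length(numerator) == 0 || length(denominator) == 0)
    stop("beta_margin: index sets must be non-empty", call. = FALSE)
  if (!all(numerator %in% seq_len(m)) || !all(denominator %in% seq_len(m)))
    stop("beta_margin: index out of range", call. = FALSE)
  if (!all(numerator %in% denominator))
    stop("beta_margin: numerator must be contained in denominator", call. = FALSE)
  rest <- setdiff(denominator, numerator)
  if (length(rest) == 0)
    stop("beta_margin: numerator equal to denominator gives a degenerate ratio of 1",
         call. = FALSE)
  beta_posterior(sum(posterior$alpha[numerator]), sum(posterior$alpha[rest]))
}

#' Posterior mean of a Beta distribution
#'
#' @param x A `beta_posterior`.
#' @return `a / (a + b)`.
#' @export
beta_mean <- function(x) {
  stopifnot(inherits(x, "beta_posterior"))
  x$a / (x$a + x$b)
}

# Shared print/coef plumbing for fitted objects that carry a
# posterior_table in $summary.
#' @export
print.dta_fit <- function(x, ...) {
  cat(x$title, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
summary.dta_fit <- function(object, ...) object$summary

#' @export
coef.dta_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

new_dta_fit <- function(subclass, title, summaries, draws, extra = list()) {
  obj <- c(list(title = title,
                summary = posterior_table(summaries),
                draws = draws),
           extra)
  structure(obj, class = c(subclass, "dta_fit"))
}
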