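# Accuracy of combined tests: believe-the-positive / believe-the-negative
# rules for paired binary tests, likelihood-ratio optimal ROC utilities,
# and the risk-score (Bayesian logistic regression) pipeline.

#' Posterior accuracy of BP and BN combination rules
#'
#' For two binary tests applied to the same subjects, the
#' believe-the-positive (BP) rule calls a subject positive when *either*
#' test is positive, and the believe-the-negative (BN) rule only when
#' *both* are.  Independent uniform-prior Dirichlet posteriors are placed
#' on the diseased and non-diseased (test1, test2) cell probabilities;
#' per draw the rule fractions are plain cell-probability sums:
#' `tpf_bp = theta01 + theta10 + theta11`, `tpf_bn = theta11`, and the
#' FPF analogues on the non-diseased cells.
#'
#' Per draw the BP rule can only gain sensitivity (`tpf_bp >= max(tpf1,
#' tpf2)`, `fpf_bp <= fpf1 + fpf2`) and the BN rule can only lose it
#' (`tpf_bn >= tpf1 + tpf2 - 1`, `fpf_bn <= min(fpf1, fpf2)`).
#'
#' @param tables A `paired_binary_counts`.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `combined_binary_fit` with summaries `tpf1`, `fpf1`, `tpf2`,
#'   `fpf2`, `tpf_bp`, `fpf_bp`, `tpf_bn`, `fpf_bn`.
#' @export
bp_bn_posteriors <- function(tables, n_draws = 25000, seed = 1) {
  stopifnot(inherits(tables, "paired_binary_counts"))
  post_d <- dirichlet_posterior(as.vector(t(tables$diseased)))
  post_n <- dirichlet_posterior(as.vector(t(tables$nondiseased)))
  th <- draw(post_d, n_draws, seed)
  ph <- draw(post_n, n_draws, seed = NULL)
  draws <- cbind(
    tpf1 = th[, CELL10] + th[, CELL11], fpf1 = ph[, CELL10] + ph[, CELL11],
    tpf2 = th[, CELL01] + th[, CELL11], fpf2 = ph[, CELL01] + ph[, CELL11],
    tpf_bp = th[, CELL01] + th[, CELL10] + th[, CELL11],
    fpf_bp = ph[, CELL01] + ph[, CELL10] + ph[, CELL11],
    tpf_bn = th[, CELL11], fpf_bn = ph[, CELL11])
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("combined_binary_fit",
              "BP/BN combination rules for two binary tests",
              sums, draws,
              list(posterior_diseased = post_d, posterior_nondiseased = post_n,
                   seed = seed, tables = tables))
}

#' Truncated (conditional) cell probabilities
#'
#' Normalises a 2x2 joint cell-probability matrix over its first index,
#' giving P(test1 = i | test2 = j).  Exposed for completeness; the BP/BN
#' fractions use the plain joint cell probabilities.
#'
#' @param m A 2x2 matrix of non-negative cell probabilities.
#' @return The column-normalised matrix.
#' @export
truncated_cell_probs <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 2), all(m >= 0))
  sweep(m, 2, colSums(m), "/")
}

#' Likelihood-ratio optimal ROC for a discrete joint distribution
#'
#' Orders the cells of a discrete score distribution by decreasing
#' likelihood ratio `LR = theta_cell / phi_cell` (ties grouped; cells
#' with `phi = 0 < theta` rank first with `LR = Inf`) and accumulates
#' (FPF, TPF) points.  By the Neyman-Pearson lemma no decision rule
#' achieves a higher TPF at equal FPF, so the trapezoid area under these
#' points is the maximal attainable ROC area for any combination rule on
#' the same scores.
#'
#' @param theta,phi Non-negative cell probabilities of the diseased and
#'   non-diseased score distributions; each must sum to 1.
#' @return A list with `points` (data frame `fpf`, `tpf`, `lr`, starting
#'   at (0,0)), `area`, and the per-cell `lr` in input order.
#' @export
lr_roc <- function(theta, phi) {
  if (length(theta) != length(phi))
    stop("lr_roc: theta and phi must have equal length", call. = FALSE)
  if (any(theta < 0) || any(phi < 0) ||
      abs(sum(theta) - 1) > 1e-8 || abs(sum(phi) - 1) > 1e-8)
    stop("lr_roc: theta and phi must be probability vectors", call. = FALSE)
  keep <- theta > 0 | phi > 0
  lr_all <- ifelse(phi > 0, theta / phi, ifelse(theta > 0, Inf, NA_real_))
  th <- theta[keep]; ph <- phi[keep]; lr <- lr_all[keep]
  groups <- sort(unique(lr), decreasing = TRUE)
  tpf <- cumsum(vapply(groups, function(g) sum(th[lr == g]), 0))
  fpf <- cumsum(vapply(groups, function(g) sum(ph[lr == g]), 0))
  pts <- data.frame(fpf = c(0, fpf), tpf = c(0, tpf), lr = c(Inf, groups))
  area <- sum(diff(pts$fpf) * (utils::head(pts$tpf, -1) + utils::tail(pts$tpf, -1)) / 2)
  list(points = pts, area = area, lr = lr_all)
}

#' Operating characteristics along the likelihood-ratio ROC
#'
#' Evaluates, at each likelihood-ratio threshold, the misclassification
#' probability `rho*(1 - TPF) + (1 - rho)*FPF` and the expected cost
#' `cost_fn*rho*(1 - TPF) + cost_fp*(1 - rho)*FPF`, where `rho` is the
#' disease prevalence.  The LR rule minimises both over all rules.
#'
#' @param theta,phi As in [lr_roc()].
#' @param prevalence Disease rate `rho` in (0, 1).
#' @param cost_fp,cost_fn Unit costs of false positive / false negative
#'   errors.
#' @return The `lr_roc()` points with `misclassification` and
#'   `expected_cost` columns appended.
#' @export
lr_operating_points <- function(theta, phi, prevalence,
                                cost_fp = 1, cost_fn = 1) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("lr_operating_points: prevalence must lie in (0,1)", call. = FALSE)
  pts <- lr_roc(theta, phi)$points
  pts$misclassification <- prevalence * (1 - pts$tpf) + (1 - prevalence) * pts$fpf
  pts$expected_cost <- cost_fn * prevalence * (1 - pts$tpf) +
    cost_fp * (1 - prevalence) * pts$fpf
  pts
}

#' AUC of a discrete score under known class distributions
#'
#' `P(S_D > S_Dbar) + P(S_D = S_Dbar)/2` for a score taking value
#' `values[i]` with probability `probs_d[i]` among diseased and
#' `probs_nd[i]` among non-diseased subjects.
#'
#' @param values Score attached to each cell.
#' @param probs_d,probs_nd Cell probabilities for the diseased and
#'   non-diseased populations (each sums to 1).
#' @return The AUC.
#' @export
discrete_score_auc <- function(values, probs_d, probs_nd) {
  stopifnot(length(values) == length(probs_d),
            length(values) == length(probs_nd))
  gt <- outer(values, values, ">")
  eq <- outer(values, values, "==")
  sum(probs_d * (gt %*% probs_nd)) + 0.5 * sum(probs_d * (eq %*% probs_nd))
}

#' Bayesian logistic regression risk score
#'
#' Fits `logit P(D=1 | Y) = b1 + b2*Y1 + ... ` with independent
#' normal(0, precision `prior_prec`) priors on the coefficients, by
#' random-walk Metropolis-within-Gibbs with per-coefficient step sizes
#' adapted during burn-in towards an acceptance rate of 0.3-0.45.
#' Identical covariate rows are aggregated into binomial observations, so
#' ordinal test scores cost nothing extra.  The risk score of a subject
#' is the posterior mean of `plogis(b %*% y)`.
#'
#' @param subjects A data frame with a 0/1 column `d` and one or more
#'   numeric predictor columns (the component test scores; add squares or
#'   cross-products as extra columns if wanted).
#' @param prior_prec Prior precision of the coefficients.
#' @param n_iter,burnin Chain length and discarded portion.
#' @param seed Integer seed.
#' @return A `risk_score_fit` with coefficient summaries (`b1` is the
#'   intercept), per-subject posterior-mean `risk_scores`, acceptance
#'   rates and retained coefficient draws.
#' @export
fit_risk_score <- function(subjects, prior_prec = 1e-4, n_iter = 45000,
                           burnin = 5000, seed = 1) {
  stopifnot(is.data.frame(subjects), "d" %in% names(subjects))
  d <- subjects$d
  if (!all(d %in% c(0, 1))) stop("fit_risk_score: d must be 0/1", call. = FALSE)
  if (!any(d == 0) || !any(d == 1))
    stop("fit_risk_score: both disease labels must be present", call. = FALSE)
  if (n_iter <= burnin || burnin < 0)
    stop("fit_risk_score: need n_iter > burnin >= 0", call. = FALSE)
  X <- as.matrix(cbind(1, subjects[setdiff(names(subjects), "d")]))
  colnames(X)[1] <- "(intercept)"
  p <- ncol(X)
  # aggregate identical covariate rows into binomial observations
  key <- apply(X, 1, paste, collapse = "\r")
  agg_y <- tapply(d, key, sum)
  agg_m <- tapply(d, key, length)
  Xu <- X[match(names(agg_y), key), , drop = FALSE]
  y <- as.vector(agg_y); mtot <- as.vector(agg_m)

  # separation check via a quiet ML fit
  sep <- FALSE
  withCallingHandlers(
    stats::glm.fit(Xu, y / mtot, weights = mtot,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep)
    warning("fit_risk_score: data show (quasi-)separation; the posterior is ",
            "proper under the normal prior but coefficients are prior-driven")

  if (!is.null(seed)) set.seed(seed)
  loglik <- function(b) {
    eta <- drop(Xu %*% b)
    # numerically stable log(1 + exp(eta))
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    sum(y * eta - mtot * lse) - 0.5 * prior_prec * sum(b * b)
  }
  b <- rep(0, p)
  ll <- loglik(b)
  step <- rep(0.1, p)
  acc <- integer(p); tries <- integer(p)
  keep <- n_iter - burnin
  out <- matrix(NA_real_, keep, p,
                dimnames = list(NULL, paste0("b", seq_len(p))))
  rs_sum <- numeric(nrow(Xu))
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- b
      prop[j] <- b[j] + stats::rnorm(1, 0, step[j])
      llp <- loglik(prop)
      tries[j] <- tries[j] + 1L
      if (log(stats::runif(1)) < llp - ll) {
        b <- prop; ll <- llp; acc[j] <- acc[j] + 1L
      }
    }
    if (it <= burnin && it %% 100 == 0) {
      rate <- acc / pmax(tries, 1)
      step <- step * exp(0.5 * (rate - 0.375))
      acc[] <- 0L; tries[] <- 0L
    }
    if (it > burnin) {
      out[it - burnin, ] <- b
      rs_sum <- rs_sum + stats::plogis(drop(Xu %*% b))
    }
  }
  rs_unique <- rs_sum / keep
  risk_scores <- rs_unique[match(key, names(agg_y))]
  sums <- lapply(colnames(out), function(par) summarize_draws(out[, par], par))
  names(sums) <- colnames(out)
  new_dta_fit("risk_score_fit", "Bayesian logistic regression risk score",
              sums, out,
              list(risk_scores = risk_scores, labels = d,
                   acceptance = acc / pmax(tries, 1), seed = seed,
                   n_iter = n_iter, burnin = burnin, separation = sep))
}

#' ROC area of a fitted risk score
#'
#' Either feeds the posterior-mean risk scores into the binormal Gibbs
#' sampler by disease label (`method = "binormal"`, the default,
#' mirroring the two-stage pipeline of the reference analyses) or
#' computes the empirical Mann-Whitney area
#' `P(RS_D > RS_Dbar) + P(=)/2` directly (`method = "mann-whitney"`,
#' appropriate since risk scores are generally not normal).
#'
#' @param model A `risk_score_fit`.
#' @param method `"binormal"` or `"mann-whitney"`.
#' @param ... For the binormal route, arguments passed to
#'   [fit_binormal()] (e.g. `n_iter`, `burnin`, `seed`).
#' @return For `"binormal"`, the `binormal_fit` (its `auc` row is the
#'   risk-score ROC area); for `"mann-whitney"`, a list with `method` and
#'   `auc`.
#' @export
risk_score_auc <- function(model, method = c("binormal", "mann-whitney"), ...) {
  stopifnot(inherits(model, "risk_score_fit"))
  method <- match.arg(method)
  rs <- model$risk_scores
  d <- model$labels
  if (diff(range(rs)) < 1e-12)
    stop("risk_score_auc: all risk scores are identical", call. = FALSE)
  if (method == "mann-whitney") {
    list(method = method, auc = mann_whitney_auc(rs[d == 1], rs[d == 0]))
  } else {
    fit_binormal(score_set(rs, d), ...)
  }
}

#' Empirical Mann-Whitney AUC
#'
#' `P(score_d > score_nd) + P(score_d = score_nd)/2` over all pairs,
#' computed via midranks.
#'
#' @param scores_d,scores_nd Scores of the diseased and non-diseased
#'   subjects.
#' @return The empirical AUC.
#' @export
mann_whitney_auc <- function(scores_d, scores_nd) {
  n1 <- length(scores_d); n0 <- length(scores_nd)
  if (n1 == 0 || n0 == 0)
    stop("mann_whitney_auc: both groups must be non-empty", call. = FALSE)
  r <- rank(c(scores_d, scores_nd))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior marginal ROC areas of two paired ordinal tests
#'
#' Places independent uniform-prior Dirichlet posteriors on the k x k
#' joint cell probabilities of the diseased and the non-diseased
#' subjects (rows = test1 score, columns = test2 score); per draw
#' collapses each joint to the two tests' margins and computes each
#' test's ordinal ROC area `Area = A1 + A2/2`.
#'
#' @param joint_diseased,joint_nondiseased k x k count matrices.
#' @param n_draws Monte Carlo sample size.
#' @param seed Integer seed.
#' @return A `marginal_auc_fit` with summaries `area1`, `a11`, `a12`,
#'   `area2`, `a21`, `a22` (the per-test areas and their P(>) and P(=)
#'   components).
#' @export
marginal_ordinal_aucs <- function(joint_diseased, joint_nondiseased,
                                  n_draws = 45000, seed = 1) {
  jd <- as.matrix(joint_diseased); jn <- as.matrix(joint_nondiseased)
  if (nrow(jd) != ncol(jd) || !all(dim(jd) == dim(jn)))
    stop("marginal_ordinal_aucs: joints must be square and of equal size",
         call. = FALSE)
  k <- nrow(jd)
  check_counts(jd, "marginal_ordinal_aucs diseased")
  check_counts(jn, "marginal_ordinal_aucs nondiseased")
  post_d <- dirichlet_posterior(as.vector(jd))
  post_n <- dirichlet_posterior(as.vector(jn))
  th <- draw(post_d, n_draws, seed)
  ph <- draw(post_n, n_draws, seed = NULL)
  # cell -> margin collapse matrices (cells stored column-major)
  rows <- factor(rep(seq_len(k), k)); cols <- factor(rep(seq_len(k), each = k))
  M1 <- stats::model.matrix(~ rows - 1)       # test1 margin
  M2 <- stats::model.matrix(~ cols - 1)       # test2 margin
  area_component <- function(tm, pm) {
    below <- cbind(0, t(apply(pm, 1, cumsum)))[, 1:k, drop = FALSE]
    a1 <- rowSums(tm * below)
    a2 <- rowSums(tm * pm)
    cbind(a1 + a2 / 2, a1, a2)
  }
  c1 <- area_component(th %*% M1, ph %*% M1)
  c2 <- area_component(th %*% M2, ph %*% M2)
  draws <- cbind(area1 = c1[, 1], a11 = c1[, 2], a12 = c1[, 3],
                 area2 = c2[, 1], a21 = c2[, 2], a22 = c2[, 3])
  sums <- lapply(colnames(draws), function(p) summarize_draws(draws[, p], p))
  names(sums) <- colnames(draws)
  new_dta_fit("marginal_auc_fit",
              "Marginal ROC areas of two paired ordinal tests",
              sums, draws,
              list(posterior_diseased = post_d, posterior_nondiseased = post_n,
                   seed = seed, k = k))
}
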