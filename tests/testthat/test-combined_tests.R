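test_that("BP/BN posterior means match the Dirichlet closed forms", {
  fit <- bp_bn_posteriors(load_fixture("stenosis"), n_draws = 20000, seed = 51)
  s <- summary(fit)
  exact <- c(tpf_bn = 37 / 62, tpf1 = 48 / 62, tpf2 = 38 / 62,
             tpf_bp = 49 / 62, fpf_bn = 39 / 240, fpf1 = 70 / 240)
  for (m in names(exact)) {
    row <- s[s$parameter == m, ]
    expect_lt(abs(row$mean - exact[[m]]), 4 * row$mc_error)
  }
})

test_that("BP gains and BN loses sensitivity per draw, within the
           Frechet bounds", {
  for (sd_seed in c(52, 53)) {
    tabs <- gen_paired_binary(120, 150,
                              theta = matrix(c(0.1, 0.2, 0.15, 0.55), 2, 2),
                              phi = matrix(c(0.55, 0.2, 0.15, 0.1), 2, 2),
                              seed = sd_seed)
    d <- bp_bn_posteriors(tabs, n_draws = 2000, seed = sd_seed)$draws
    expect_true(all(d[, "tpf_bp"] >= pmax(d[, "tpf1"], d[, "tpf2"]) - 1e-14))
    expect_true(all(d[, "fpf_bp"] <= d[, "fpf1"] + d[, "fpf2"] + 1e-14))
    expect_true(all(d[, "tpf_bn"] >= d[, "tpf1"] + d[, "tpf2"] - 1 - 1e-14))
    expect_true(all(d[, "fpf_bn"] <= pmin(d[, "fpf1"], d[, "fpf2"]) + 1e-14))
  }
})

test_that("an always-double-positive diseased group gives the Beta limit", {
  n <- 200
  tabs <- paired_binary_counts(matrix(c(0, 0, 0, n), 2, 2),
                               matrix(c(50, 10, 10, 5), 2, 2))
  fit <- bp_bn_posteriors(tabs, n_draws = 20000, seed = 54)
  s <- summary(fit)
  row <- s[s$parameter == "tpf_bn", ]
  expect_lt(abs(row$mean - (n + 1) / (n + 4)), 4 * row$mc_error)
})

test_that("the likelihood-ratio ROC matches hand computation", {
  out <- lr_roc(theta = c(0.7, 0.3), phi = c(0.2, 0.8))
  expect_equal(out$lr, c(3.5, 0.375))
  expect_equal(out$points$fpf, c(0, 0.2, 1))
  expect_equal(out$points$tpf, c(0, 0.7, 1))
  expect_equal(out$area, 0.75)
  # theta == phi: chance line
  expect_equal(lr_roc(c(0.3, 0.7), c(0.3, 0.7))$area, 0.5)
  # zero-phi cell ranks first with infinite LR
  out2 <- lr_roc(c(0.5, 0.5), c(0, 1))
  expect_equal(out2$points$tpf[2], 0.5)
  expect_equal(out2$points$fpf[2], 0)
  expect_equal(out2$area, 0.75)
  expect_error(lr_roc(c(0.5, 0.6), c(0.5, 0.5)), "probability")
})

test_that("no deterministic rule beats the LR rule on a 3-cell grid", {
  set.seed(55)
  for (rep in 1:10) {
    theta <- as.vector(rdirichlet(1, rep(1, 3)))
    phi <- as.vector(rdirichlet(1, rep(1, 3)))
    opt <- lr_roc(theta, phi)
    rules <- all_rule_points(theta, phi)
    hull_tpf <- roc_at(opt$points, rules[, "fpf"])
    expect_true(all(rules[, "tpf"] <= hull_tpf + 1e-12))
  }
})

test_that("misclassification along the LR ROC is minimised at the
           prevalence-matched threshold", {
  pts <- lr_operating_points(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6),
                             prevalence = 0.3)
  expect_true(all(pts$misclassification >= 0 & pts$misclassification <= 1))
  # with unit costs expected cost equals misclassification
  expect_equal(pts$expected_cost, pts$misclassification)
  # any deterministic rule does at least as badly
  rules <- all_rule_points(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6))
  best_rule <- min(0.3 * (1 - rules[, "tpf"]) + 0.7 * rules[, "fpf"])
  expect_lte(min(pts$misclassification), best_rule + 1e-12)
})

test_that("true-probability risk scores attain the LR ROC area exactly", {
  theta <- c(0.5, 0.3, 0.2); phi <- c(0.1, 0.3, 0.6)
  rs <- true_risk_scores(theta, phi, prevalence = 0.25)
  expect_equal(discrete_score_auc(rs, theta, phi), lr_roc(theta, phi)$area,
               tolerance = 1e-14)
})

test_that("logistic coefficients are recovered from synthetic subjects", {
  truth <- c(-2, 0.4, 0.3)
  subjects <- gen_logistic_subjects(2000, truth, seed = 56)
  fit <- fit_risk_score(subjects, n_iter = 8000, burnin = 2000, seed = 57)
  est <- coef(fit)
  expect_lt(max(abs(est - truth)), 0.15)
  expect_true(all(fit$risk_scores > 0 & fit$risk_scores < 1))
})

test_that("collinear predictors keep their sum identified", {
  subjects <- gen_logistic_subjects(1500, c(-1.5, 0.5), seed = 58)
  single <- fit_risk_score(subjects, n_iter = 6000, burnin = 1500, seed = 59)
  dup <- subjects; dup$T2 <- dup$T1
  both <- fit_risk_score(dup[, c("T1", "T2", "d")], n_iter = 6000,
                         burnin = 1500, seed = 59)
  expect_lt(abs((coef(both)[["b2"]] + coef(both)[["b3"]]) -
                  coef(single)[["b2"]]), 0.15)
})

test_that("degenerate outcomes and constant risk scores are refused", {
  bad <- data.frame(T1 = 1:10, d = rep(1, 10))
  expect_error(fit_risk_score(bad), "both disease labels")
})

test_that("Mann-Whitney area is 1 for perfectly separated risk scores", {
  subjects <- data.frame(T1 = c(rep(0, 30), rep(10, 30)),
                         d = c(rep(0, 30), rep(1, 30)))
  fit <- suppressWarnings(
    fit_risk_score(subjects, n_iter = 3000, burnin = 1000, seed = 60))
  mw <- risk_score_auc(fit, "mann-whitney")
  expect_equal(mw$auc, 1)
})

test_that("marginal ordinal areas match the aggregated-Dirichlet oracle", {
  joints <- gen_ordinal_joint(400, 500,
                              theta = outer(c(0.1, 0.15, 0.2, 0.25, 0.3),
                                            c(0.1, 0.2, 0.3, 0.25, 0.15)),
                              phi = outer(c(0.4, 0.25, 0.2, 0.1, 0.05),
                                          c(0.3, 0.3, 0.2, 0.1, 0.1)),
                              seed = 61)
  fit <- marginal_ordinal_aucs(joints$diseased, joints$nondiseased,
                               n_draws = 20000, seed = 62)
  s <- summary(fit)
  k <- 5
  # collapsing a cellwise Dirichlet(counts + 1) to a margin gives a
  # Dirichlet with alpha = margin counts + k; the area is bilinear, so
  # its mean is exact at the aggregated means
  agg <- function(counts_margin) {
    structure(list(alpha = counts_margin + k), class = "dirichlet_posterior")
  }
  exact1 <- auc_ordinal_expectation(agg(rowSums(joints$diseased)),
                                    agg(rowSums(joints$nondiseased)))
  exact2 <- auc_ordinal_expectation(agg(colSums(joints$diseased)),
                                    agg(colSums(joints$nondiseased)))
  a1 <- s[s$parameter == "area1", ]; a2 <- s[s$parameter == "area2", ]
  expect_lt(abs(a1$mean - exact1), 4 * a1$mc_error)
  expect_lt(abs(a2$mean - exact2), 4 * a2$mc_error)
  d <- fit$draws
  expect_equal(unname(d[, "area1"]),
               unname(d[, "a11"] + d[, "a12"] / 2), tolerance = 1e-14)
})

test_that("concentrated identity joints give areas near 1, flat joints 1/2", {
  k <- 3
  conc <- diag(k) * 300 + 1
  flat <- matrix(20, k, k)
  top <- matrix(0, k, k); top[k, k] <- 300
  bottom <- matrix(0, k, k); bottom[1, 1] <- 300
  fit <- marginal_ordinal_aucs(top, bottom, n_draws = 5000, seed = 63)
  expect_gt(coef(fit)[["area1"]], 0.9)
  fit2 <- marginal_ordinal_aucs(flat, flat, n_draws = 5000, seed = 64)
  expect_lt(abs(coef(fit2)[["area1"]] - 0.5), 0.02)
})

test_that("truncated cell probabilities normalise over the first index", {
  m <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  tr <- truncated_cell_probs(m)
  expect_equal(colSums(tr), c(1, 1), ignore_attr = TRUE)
})
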