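test_that("cell assignment probabilities follow Bayes' theorem per cell", {
  m <- cell_assignment_probs(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(unname(m), rep(0.5, 4))
  m2 <- cell_assignment_probs(0.5, 0.9, 0.9, 0.9, 0.9)
  expect_equal(m2[["m11"]], 0.81 / 0.82, tolerance = 1e-12)
  expect_equal(m2[["m00"]], 0.01 / 0.82, tolerance = 1e-12)
  m3 <- cell_assignment_probs(1 - 1e-9, 0.8, 0.9, 0.95, 0.85)
  expect_true(all(m3 > 0.999))
  expect_error(cell_assignment_probs(0, 0.5, 0.5, 0.5, 0.5), "strictly")
})

test_that("apparent accuracy relative to the reference matches the
           published fractions", {
  ovr <- observed_vs_reference(load_fixture("strongyloides"))
  expect_equal(ovr$sensitivity, 38 / 125, tolerance = 1e-12)
  expect_equal(ovr$specificity, 35 / 37, tolerance = 1e-12)
  demo <- observed_vs_reference(load_fixture("reference_standard_demo"))
  expect_equal(demo$sensitivity, 0.8, tolerance = 1e-12)
  expect_equal(demo$specificity, 74 / 120, tolerance = 1e-12)
  # T identical to R
  ident <- nogold_crosstab(matrix(c(50, 0, 0, 50), 2, 2))
  expect_equal(observed_vs_reference(ident),
               list(sensitivity = 1, specificity = 1))
})

test_that("chain state stays inside its support", {
  fit <- gibbs_no_gold(load_fixture("strongyloides"), lc_priors(),
                       n_iter = 2000, burnin = 200, seed = 41)
  expect_true(all(fit$draws > 0 & fit$draws < 1))
  expect_equal(colnames(fit$draws), c("p", "s1", "s2", "c1", "c2"))
})

test_that("with accuracies pinned at truth the prevalence posterior matches
           brute-force enumeration of the latent configurations", {
  n <- matrix(c(2, 1, 1, 2), 2, 2)   # tiny table, n.. = 6
  truth <- list(s1 = 0.8, c1 = 0.9, s2 = 0.85, c2 = 0.8)
  exact <- exact_nogold_p_mean(n, truth$s1, truth$c1, truth$s2, truth$c2)
  conc <- 1e7   # effectively point-mass priors at the true accuracies
  pri <- lc_priors(p = c(1, 1),
                   s1 = conc * c(truth$s1, 1 - truth$s1),
                   s2 = conc * c(truth$s2, 1 - truth$s2),
                   c1 = conc * c(truth$c1, 1 - truth$c1),
                   c2 = conc * c(truth$c2, 1 - truth$c2))
  fit <- gibbs_no_gold(nogold_crosstab(n), pri, n_iter = 30000, burnin = 2000,
                       seed = 42)
  s <- summary(fit)
  p_row <- s[s$parameter == "p", ]
  expect_lt(abs(p_row$mean - exact), 4 * p_row$mc_error + 0.005)
})

test_that("under uniform priors the posterior shows the label-switching
           ambiguity", {
  fit <- gibbs_no_gold(load_fixture("strongyloides"), lc_priors(),
                       n_iter = 60000, burnin = 5000, seed = 43)
  p <- fit$draws[, "p"]
  # the likelihood is invariant under (p,s,c) -> (1-p,1-c,1-s); the chain
  # must visit both modes, giving a broad, near-symmetric p posterior
  expect_gt(sd(p), 0.12)
  expect_gt(mean(p < 0.35), 0.05)
  expect_gt(mean(p > 0.65), 0.05)
})

test_that("parameters are recovered from synthetic data with informative
           priors centred at truth", {
  truth <- list(p = 0.6, s1 = 0.8, s2 = 0.9, c1 = 0.95, c2 = 0.85)
  counts <- gen_no_gold(5000, truth$p, truth$s1, truth$c1, truth$s2, truth$c2,
                        seed = 44)
  conc <- 50
  pri <- lc_priors(p = c(1, 1),
                   s1 = conc * c(truth$s1, 1 - truth$s1),
                   s2 = conc * c(truth$s2, 1 - truth$s2),
                   c1 = conc * c(truth$c1, 1 - truth$c1),
                   c2 = conc * c(truth$c2, 1 - truth$c2))
  fit <- gibbs_no_gold(counts, pri, n_iter = 20000, burnin = 2000, seed = 45)
  est <- coef(fit)
  for (par in names(truth))
    expect_lt(abs(est[[par]] - truth[[par]]), 0.05)
})
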