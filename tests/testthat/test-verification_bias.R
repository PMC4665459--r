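test_that("naive estimates are the verified-subset fractions", {
  nv <- naive_estimates(load_fixture("scintigraphy"))
  expect_equal(nv$sensitivity, 298 / 329, tolerance = 1e-12)
  expect_equal(nv$fpf, 26 / 74, tolerance = 1e-12)
  # fully verified perfect test
  nv2 <- naive_estimates(verification_counts(s = c(0, 40), r = c(25, 0),
                                             u = c(0, 0)))
  expect_equal(nv2$sensitivity, 1)
  expect_equal(nv2$fpf, 0)
  nv3 <- naive_estimates(verification_counts(c(1, 1), c(1, 1), c(0, 0)))
  expect_equal(nv3$sensitivity, 0.5)
  expect_equal(nv3$fpf, 0.5)
  expect_error(naive_estimates(verification_counts(c(0, 0), c(1, 1), c(2, 2))),
               "verified")
})

test_that("full verification reduces to the standard 2x2 analysis", {
  tab <- count_table_2x2(327, 208, 115, 818)
  v <- verification_counts(s = c(208, 818), r = c(327, 115), u = c(0, 0))
  corrected <- corrected_binary(v, n_draws = 30000, seed = 31)
  basic <- basic_measures(tab, n_draws = 30000, seed = 32)
  cs <- summary(corrected); bs <- summary(basic)
  tol <- 4 * (cs$mc_error[cs$parameter == "tpf"] +
                bs$mc_error[bs$parameter == "TPF"]) + 0.002
  expect_lt(abs(cs$mean[cs$parameter == "tpf"] -
                  bs$mean[bs$parameter == "TPF"]), tol)
  expect_lt(abs(cs$mean[cs$parameter == "fpf"] -
                  bs$mean[bs$parameter == "FPF"]), tol)
})

test_that("uninformative test results collapse the corrected TPF to the
           positive-result probability", {
  # same verified disease mix in both result categories: phi1 = phi0 in
  # distribution, so alpha1 degenerates to theta1 by Bayes' theorem
  v <- verification_counts(s = c(50, 50), r = c(50, 50), u = c(10, 10))
  fit <- corrected_binary(v, n_draws = 30000, seed = 33)
  s <- summary(fit)
  expect_lt(abs(s$mean[s$parameter == "tpf"] - 0.5), 0.01)
})

test_that("corrected ordinal fractions are simplex-valued per draw", {
  fit <- corrected_ordinal_auc(load_fixture("mammography_verification"),
                               n_draws = 2000, seed = 34)
  expect_true(all(abs(rowSums(fit$alpha_draws) - 1) < 1e-12))
  expect_true(all(abs(rowSums(fit$beta_draws) - 1) < 1e-12))
  d <- fit$draws
  expect_equal(unname(d[, "A"]),
               unname(d[, "A1"] + d[, "tie_prob"] / 2), tolerance = 1e-14)
  expect_equal(unname(d[, "A2"] * 2), unname(d[, "tie_prob"]), tolerance = 1e-14)
})

test_that("the plug-in area lies inside the posterior interval", {
  v <- load_fixture("mammography_verification")
  fit <- corrected_ordinal_auc(v, n_draws = 20000, seed = 35)
  s <- summary(fit)
  # plug-in oracle: evaluate the Bayes-theorem pipeline at posterior means
  phi <- (v$s + 1) / (v$s + v$r + 2)
  theta <- (v$m + 1) / sum(v$m + 1)
  pd <- sum(phi * theta)
  alpha <- phi * theta / pd
  beta <- (1 - phi) * theta / (1 - pd)
  a1 <- sum(alpha * c(0, cumsum(beta))[1:v$k])
  plug <- a1 + sum(alpha * beta) / 2
  arow <- s[s$parameter == "A", ]
  expect_gt(plug, arow$q025)
  expect_lt(plug, arow$q975)
  expect_lt(abs(arow$mean - plug), 0.01)
})

test_that("perfectly separated categories drive the corrected area to 1", {
  v <- verification_counts(s = c(0, 0, 120), r = c(150, 0, 0), u = c(5, 0, 5))
  fit <- corrected_ordinal_auc(v, n_draws = 10000, seed = 36)
  expect_gt(coef(fit)[["A"]], 0.95)
})
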