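# Independent oracles used across test files.

# Brute-force ROC dominance: tpf/fpf of every deterministic positivity
# rule (subset of cells called positive) on a discrete joint.
all_rule_points <- function(theta, phi) {
  k <- length(theta)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  t(apply(subsets, 1, function(s)
    c(fpf = sum(phi[unlist(s)]), tpf = sum(theta[unlist(s)]))))
}

# linear interpolation of an ROC polyline at a given fpf
roc_at <- function(points, fpf) {
  stats::approx(points$fpf, points$tpf, xout = fpf, ties = max)$y
}

# Exact posterior of the prevalence in the tiny no-gold-standard model
# when sensitivities/specificities are fixed at known values: a mixture
# of Beta(y.. + 1, n.. - y.. + 1) over all latent configurations.
exact_nogold_p_mean <- function(n, s1, c1, s2, c2) {
  # n is a 2x2 matrix rows R=0,1 cols T=0,1
  f_d <- function(i, j) s1^j * (1 - s1)^(1 - j) * s2^i * (1 - s2)^(1 - i)
  f_nd <- function(i, j) c1^(1 - j) * (1 - c1)^j * c2^(1 - i) * (1 - c2)^i
  cells <- expand.grid(i = 0:1, j = 0:1)
  grids <- lapply(seq_len(4), function(c_idx) {
    0:n[cells$i[c_idx] + 1, cells$j[c_idx] + 1]
  })
  cfg <- expand.grid(grids)
  ntot <- sum(n)
  logw <- numeric(nrow(cfg))
  for (c_idx in seq_len(4)) {
    i <- cells$i[c_idx]; j <- cells$j[c_idx]
    nc <- n[i + 1, j + 1]; y <- cfg[[c_idx]]
    logw <- logw + lchoose(nc, y) + y * log(f_d(i, j)) +
      (nc - y) * log(f_nd(i, j))
  }
  ysum <- rowSums(cfg)
  logw <- logw + lbeta(ysum + 1, ntot - ysum + 1)
  w <- exp(logw - max(logw)); w <- w / sum(w)
  # mixture mean of Beta(ysum+1, ntot-ysum+1)
  sum(w * (ysum + 1) / (ntot + 2))
}

# risk score per cell from true probabilities
true_risk_scores <- function(theta, phi, prevalence) {
  prevalence * theta / (prevalence * theta + (1 - prevalence) * phi)
}
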