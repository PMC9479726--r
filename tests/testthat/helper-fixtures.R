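# Shared fixture builders.  Everything is generated in code; no data files.

# Small deterministic dataset with phenotypic-correlation covariances.
toy_dataset <- function(L = 30, K = 2, seed = 42, rho12 = 0.4,
                        beta = c(0.5, -0.3)[seq_len(K)], gamma_noise = 0.02) {
  set.seed(seed)
  eb <- matrix(runif(L * K, 0.05, 0.25), L, K)
  es <- matrix(runif(L * K, 0.02, 0.05), L, K)
  rho <- diag(K)
  if (K >= 2) rho[rho != 1] <- rho12
  ob <- drop(eb %*% beta) + rnorm(L, 0, gamma_noise)
  os <- runif(L, 0.02, 0.05)
  mvmr_dataset(eb, es, ob, os, snpcov_phenocorr(rho, es))
}

# One simulated replicate from a reduced weak-type design.
sim_dataset <- function(n = 1500, L = 40, seed = 7, tau2 = 0,
                        scenario = "weak") {
  set.seed(seed)
  d <- mvmr_sim_design(scenario, n = n, L = L, tau2 = tau2)
  simulate_replicate(d)
}

# Literal per-SNP univariable regression loop (independent oracle for the
# summary statistics and for snpcov_individual).
lm_univar_oracle <- function(G, y) {
  out <- t(vapply(seq_len(ncol(G)), function(j) {
    fit <- stats::lm(y ~ G[, j])
    c(coef(fit)[2], summary(fit)$coefficients[2, 2])
  }, c(0, 0)))
  list(beta = out[, 1], se = out[, 2])
}

# Literal loop evaluation of Q_A (independent oracle).
qa_oracle <- function(dataset, beta, tau2 = 0) {
  total <- 0
  for (j in seq_len(dataset$L)) {
    r <- dataset$outcome_beta[j] - sum(beta * dataset$exposure_beta[j, ])
    w <- dataset$outcome_se[j]^2 +
      drop(t(beta) %*% dataset$snp_cov[[j]] %*% beta) + tau2
    total <- total + r^2 / w
  }
  total
}
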