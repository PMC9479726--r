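test_that("IVW with one exposure reduces to the closed-form ratio average", {
  d <- toy_dataset(L = 12, K = 1, seed = 1, beta = 0.4)
  est <- mvmr_ivw(d)
  w <- 1 / d$outcome_se^2
  expected <- sum(w * d$exposure_beta[, 1] * d$outcome_beta) /
    sum(w * d$exposure_beta[, 1]^2)
  expect_equal(unname(est$beta), expected, tolerance = 1e-12)
})

test_that("IVW recovers the truth under strong instruments", {
  set.seed(17)
  d <- mvmr_sim_design("three_exposure", n = 4000, L = 100)
  reps <- replicate(8, mvmr_ivw(subset_mvmr(simulate_replicate(d)$dataset,
                                            exposures = c(1, 2)))$beta[1:2])
  # two-exposure fit of the three-exposure DGP targets the confounded values,
  # so use the independent, strongly predicted exposure 2 plus exposure 1
  expect_lt(abs(mean(reps[2, ]) - (-0.3)), 0.12)
})

test_that("Q_A matches a literal element-by-element loop", {
  d <- toy_dataset(L = 17, K = 2, seed = 23)
  for (beta in list(c(0, 0), c(0.5, -0.3), c(-1.2, 2))) {
    for (tau2 in c(0, 0.37)) {
      het <- q_a(d, beta, tau2)
      expect_equal(het$value, qa_oracle(d, beta, tau2), tolerance = 1e-12)
      expect_equal(sum(het$per_snp), het$value, tolerance = 1e-12)
      expect_equal(het$dof, d$L - d$K)
      expect_equal(het$p_value,
                   pchisq(het$value, d$L - d$K, lower.tail = FALSE))
    }
  }
  # null-beta limit: pure outcome-signal Q
  het0 <- q_a(d, c(0, 0))
  expect_equal(het0$value, sum(d$outcome_beta^2 / d$outcome_se^2),
               tolerance = 1e-12)
})

test_that("Q_A is zero when the outcome associations are exactly linear", {
  d <- toy_dataset(L = 15, K = 2, seed = 31, gamma_noise = 0)
  expect_lt(q_a(d, c(0.5, -0.3))$value, 1e-18)
  expect_lt(q_ivw(d)$value, 1e-18)
})

test_that("with (near) zero covariances beta_Q equals beta_IVW and
          Q_IVW equals Q_IVW,up", {
  set.seed(19)
  L <- 40
  eb <- matrix(runif(L * 2, .05, .3), L, 2)
  es <- matrix(1e-7, L, 2)
  ob <- drop(eb %*% c(0.5, -0.3)) + rnorm(L, 0, 0.05)
  d <- mvmr_dataset(eb, es, ob, runif(L, .03, .08), snpcov_zero(es))
  ivw <- mvmr_ivw(d)$beta
  q <- mvmr_q(d)$estimate$beta
  expect_equal(q, ivw, tolerance = 1e-8)
  expect_equal(q_ivw_updated(d)$value, q_ivw(d)$value, tolerance = 1e-8)
})

test_that("no lattice point near the optimum beats the optimizer's Q_A", {
  rep <- sim_dataset(n = 900, L = 30, seed = 27)
  d <- rep$dataset
  fit <- suppressWarnings(mvmr_q(d))
  b0 <- fit$heterogeneity$beta_at_min
  grid <- expand.grid(b1 = b0[1] + seq(-0.5, 0.5, length.out = 21),
                      b2 = b0[2] + seq(-0.5, 0.5, length.out = 21))
  grid_q <- apply(grid, 1, function(b) q_a(d, as.numeric(b))$value)
  expect_lte(fit$heterogeneity$value, min(grid_q) + 1e-6)
})

test_that("Q_A is strictly decreasing in tau2 for fixed beta", {
  d <- toy_dataset(L = 20, K = 2, seed = 37)
  for (beta in list(c(0.4, -0.2), c(0, 0))) {
    vals <- vapply(c(0, .01, .05, .2, 1), function(t2) q_a(d, beta, t2)$value, 0)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("qhet truncates to tau2 = 0 when Q_A,min is already small", {
  d <- toy_dataset(L = 25, K = 2, seed = 41, gamma_noise = 0.001)
  stopifnot(suppressWarnings(mvmr_q(d))$heterogeneity$value < d$L - d$K)
  qh <- mvmr_qhet(d)
  expect_equal(qh$tau2, 0)
  expect_equal(qh$beta, suppressWarnings(mvmr_q(d))$estimate$beta,
               tolerance = 1e-10)
})

test_that("qhet solves the moment condition: Q_A(beta, tau2) = L - K", {
  for (seed in c(3, 8)) {
    rep <- sim_dataset(n = 1200, L = 50, seed = seed, tau2 = 0.5)
    d <- rep$dataset
    qh <- suppressWarnings(mvmr_qhet(d))
    expect_gt(qh$tau2, 0)
    expect_equal(q_a(d, qh$beta, qh$tau2)$value, d$L - d$K,
                 tolerance = 1e-6)
    # gradient condition: beta minimizes Q_A at the solved tau2
    for (k in 1:2) {
      bump <- qh$beta; bump[k] <- bump[k] + 1e-4
      expect_gte(q_a(d, bump, qh$tau2)$value,
                 q_a(d, qh$beta, qh$tau2)$value - 1e-8)
    }
  }
})

test_that("jackknife: identical SNP rows give zero SE; L = K + 1 errors", {
  L <- 6
  eb <- matrix(0.2, L, 1)
  es <- matrix(0.04, L, 1)
  d <- mvmr_dataset(eb, es, rep(0.1, L), rep(0.05, L), snpcov_zero(es))
  se <- jackknife_se(d, "Q")
  expect_equal(as.numeric(se), 0, tolerance = 1e-10)

  rep <- sim_dataset(n = 500, L = 3, seed = 2)
  expect_error(jackknife_se(rep$dataset, "Q"), "K \\+ 2")
})

test_that("jackknife SE tracks the sampling dispersion of beta_Q", {
  d <- mvmr_sim_design("three_exposure", n = 1500, L = 60)
  betas <- matrix(NA_real_, 30, 2)
  jk <- matrix(NA_real_, 5, 2)
  set.seed(53)
  for (r in 1:30) {
    ds <- subset_mvmr(simulate_replicate(d)$dataset, exposures = c(1, 2))
    betas[r, ] <- suppressWarnings(mvmr_q(ds))$estimate$beta
    if (r <= 5) jk[r, ] <- suppressWarnings(jackknife_se(ds, "Q"))
  }
  emp_sd <- apply(betas, 2, sd)
  jk_mean <- colMeans(jk)
  expect_true(all(abs(jk_mean - emp_sd) / emp_sd < 0.35))
})

test_that("outlier ranking: a planted pleiotropic SNP ranks first", {
  set.seed(29)
  ds <- mvmr_sim_design("custom", n = 1200, L = 40,
                        confounder = c(1, 1), theta_max = 0,
                        loading = c(0, 0), u_lo = c(-.6, -.6),
                        u_hi = c(.6, .6))
  d <- simulate_replicate(ds)$dataset
  ob <- d$outcome_beta
  ob[17] <- ob[17] + 1          # huge direct effect for one SNP
  d2 <- mvmr_dataset(d$exposure_beta, d$exposure_se, ob, d$outcome_se,
                     d$snp_cov, snp_ids = d$snp_ids)
  het <- suppressWarnings(mvmr_q(d2))$heterogeneity
  ranked <- outlier_snps(het, top_n = 3)
  expect_equal(ranked$snp[1], "snp_17")

  all_ranked <- outlier_snps(het)
  expect_equal(sum(all_ranked$contribution), het$value, tolerance = 1e-8)

  # equal contributions keep input order
  het_tie <- het
  het_tie$per_snp <- setNames(rep(1, 5), paste0("s", 1:5))
  expect_equal(outlier_snps(het_tie)$snp, paste0("s", 1:5))
})

test_that("pleiotropy report bundles the three statistics coherently", {
  rep <- sim_dataset(n = 900, L = 30, seed = 33)
  pl <- mvmr_pleiotropy(rep$dataset, top_n = 5)
  expect_named(pl, c("q_ivw", "q_ivw_up", "q_a_min", "outliers"))
  # the minimized statistic can never exceed the fixed-weight ones' own scale:
  # Q_A,min <= Q evaluated at the IVW estimate with Q_A weights
  expect_lte(pl$q_a_min$value,
             q_a(rep$dataset, pl$q_ivw$beta_at_min)$value + 1e-8)
  expect_equal(nrow(pl$outliers), 5L)
})
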