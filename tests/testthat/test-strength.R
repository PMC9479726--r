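test_that("critical values: tabulated points, interpolation, extremes", {
  expect_equal(cf_critical_value(100, "10%"), 10.84)
  expect_equal(cf_critical_value(500, "5%"), 20.50)
  expect_equal(cf_critical_value(150, "20%"), (5.64 + 5.46) / 2)
  expect_equal(cf_critical_value(25, "5%"), 21.37)
  expect_equal(cf_critical_value(800, "10%"), 10.40)   # clamped to the 500 row
  expect_equal(cf_critical_value(100, 0.1), 10.84)     # numeric level spelling
  expect_error(cf_critical_value(20, "10%"), "rule")
  expect_error(cf_critical_value(100, "15%"), "5%, 10%, 20%")
})

test_that("exact collinearity: delta = 1, Q = 0, verdicts fail-to-reject", {
  set.seed(2)
  L <- 30
  p <- runif(L, .05, .3)
  es <- matrix(0.03, L, 2)
  d <- mvmr_dataset(cbind(p, p), es, p * 0.4, rep(.03, L),
                    snpcov_phenocorr(diag(2), es))
  cd <- conditional_delta(d, 1)
  expect_equal(unname(cd$delta), 1, tolerance = 1e-12)
  cf <- conditional_F(d, 1)
  expect_equal(cf$q_x, 0, tolerance = 1e-18)
  expect_equal(cf$f_ts, 0)
  expect_true(all(cf$verdicts == "fail-to-reject"))
})

test_that("Q_x matches hand arithmetic on a 3-SNP diagonal toy", {
  # equal diagonal covariances: weights are a scalar, delta is plain OLS
  p2 <- c(1, 2, 3); p1 <- c(2, 1, 2); s <- 0.5
  es <- matrix(s, 3, 2)
  d <- mvmr_dataset(cbind(p1, p2), es, rep(.1, 3), rep(.1, 3),
                    snpcov_zero(es))
  delta_hand <- sum(p1 * p2) / sum(p2^2)            # 5/7
  resid <- p1 - delta_hand * p2
  q_hand <- sum(resid^2) / (s^2 * (1 + delta_hand^2))
  qe <- q_exposure(d, 1)
  expect_equal(unname(qe$delta), delta_hand, tolerance = 1e-10)
  expect_equal(qe$q_x, q_hand, tolerance = 1e-10)
  expect_equal(qe$p_under, pchisq(q_hand, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("F_TS * (L - (K - 1)) equals Q_x exactly, for every exposure", {
  for (seed in 1:3) {
    rep <- sim_dataset(n = 700, L = 28, seed = seed)
    for (k in 1:2) {
      cf <- conditional_F(rep$dataset, k)
      expect_equal(cf$f_ts * cf$dof, cf$q_x, tolerance = 1e-14)
      expect_equal(cf$dof, 28L - 1L)
    }
  }
})

test_that("F_TS is invariant to rescaling one exposure's units", {
  rep <- sim_dataset(n = 900, L = 30, seed = 4)
  d <- rep$dataset
  c_scale <- 3.7
  eb <- d$exposure_beta; eb[, 1] <- eb[, 1] * c_scale
  es <- d$exposure_se;  es[, 1] <- es[, 1] * c_scale
  d2 <- mvmr_dataset(eb, es, d$outcome_beta, d$outcome_se,
                     snpcov_phenocorr(rep$rho, es))
  expect_equal(mvmr_strength(d2)$f_ts, mvmr_strength(d)$f_ts,
               tolerance = 1e-8)
})

test_that("fixed-point delta agrees with direct Q_xk minimization when the
          conditional fit is exact, and closely under strong instruments", {
  # noise-free proportional effects: both approaches give delta = c, Q = 0
  L <- 26
  p2 <- seq(0.05, 0.3, length.out = L)
  cc <- 1.8
  es <- matrix(0.02, L, 2)
  d <- mvmr_dataset(cbind(cc * p2, p2), es, p2 * .3, rep(.03, L),
                    snpcov_phenocorr(matrix(c(1, .5, .5, 1), 2), es))
  qe <- q_exposure(d, 1)
  expect_equal(unname(qe$delta), cc, tolerance = 1e-8)
  expect_lt(qe$q_x, 1e-6)

  # strong instruments: the weighted-regression fixed point sits near the
  # LIML-style minimizer of Q_x1 over delta
  set.seed(15)
  d3 <- mvmr_sim_design("three_exposure", n = 4000, L = 100)
  ds <- subset_mvmr(simulate_replicate(d3)$dataset, exposures = c(1, 2))
  qe2 <- q_exposure(ds, 1)
  q_of_delta <- function(delta) {
    dstar <- c(-1, delta)
    s2 <- vapply(ds$snp_cov, function(S) drop(t(dstar) %*% S %*% dstar), 0)
    sum((ds$exposure_beta[, 1] - delta * ds$exposure_beta[, 2])^2 / s2)
  }
  direct <- optimize(q_of_delta, unname(qe2$delta) + c(-0.5, 0.5))
  expect_gte(qe2$q_x + 1e-9, direct$objective)
  expect_lt((qe2$q_x - direct$objective) / direct$objective, 0.05)
})

test_that("a singular weight variance from a degenerate covariance errors", {
  L <- 30
  p <- runif(L, .1, .3)
  es <- matrix(0.05, L, 2)
  rho1 <- matrix(c(1, 1, 1, 1), 2, 2)   # perfectly correlated errors
  d <- mvmr_dataset(cbind(p, p), es, p * .2, rep(.05, L),
                    snpcov_phenocorr(rho1, es))
  expect_error(conditional_delta(d, 1), "nonpositive weight variance")
})

test_that("collinear conditioning exposures are reported", {
  L <- 12
  p <- runif(L, .1, .3)
  es <- matrix(0.05, L, 3)
  d <- mvmr_dataset(cbind(runif(L, .1, .3), p, p), es, p * .2, rep(.05, L),
                    snpcov_phenocorr(diag(3), es))
  expect_error(conditional_delta(d, 1), "collinear")
})

test_that("strength table covers all exposures and K >= 2 is required", {
  rep <- sim_dataset(n = 700, L = 30, seed = 6)
  tab <- mvmr_strength(rep$dataset)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$f_ts > 0))
  expect_true(all(tab$verdict %in% c("reject", "fail-to-reject")))
  d1 <- subset_mvmr(rep$dataset, exposures = 1)
  expect_error(mvmr_strength(d1), "K >= 2")
})
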