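test_that("constructor accepts a clean dataset and records dimensions", {
  eb <- cbind(x1 = c(.1, .2, .3), x2 = c(.05, .1, .2))
  es <- matrix(0.05, 3, 2)
  d <- mvmr_dataset(eb, es, c(.02, .05, .08), rep(.05, 3), snpcov_zero(es))
  expect_s3_class(d, "mvmr_dataset")
  expect_equal(d$L, 3L)
  expect_equal(d$K, 2L)
  expect_equal(d$exposure_names, c("x1", "x2"))
  expect_true(all(vapply(d$snp_cov, function(S) all(S[upper.tri(S)] == 0), TRUE)))
  expect_length(validate_mvmr_dataset(d), 0)
})

test_that("constructor enforces its hard invariants", {
  es <- matrix(0.05, 3, 2)
  eb <- matrix(0.1, 3, 2)
  # too few SNPs for K = 2
  expect_error(
    mvmr_dataset(eb[1:2, ], es[1:2, ], c(.1, .2), c(.05, .05),
                 snpcov_zero(es[1:2, ])),
    "K \\+ 1")
  # nonpositive SE names the SNP
  es_bad <- es; es_bad[2, 1] <- -0.01
  expect_error(
    mvmr_dataset(eb, es_bad, rep(.1, 3), rep(.05, 3), snpcov_zero(es)),
    "snp_2")
  # covariance diagonal must match se^2
  bad_cov <- snpcov_zero(es)
  bad_cov[[1]][1, 1] <- 0.9
  expect_error(
    mvmr_dataset(eb, es, rep(.1, 3), rep(.05, 3), bad_cov),
    "disagrees with exposure_se")
})

test_that("near-PSD covariances are repaired, real violations rejected", {
  es <- matrix(0.1, 3, 2)
  eb <- matrix(0.2, 3, 2) + diag(3)[, 1:2] * 0.01
  # indefinite but within numerical-noise tolerance of PSD
  S_ok <- matrix(c(0.01, 0.0100000000005, 0.0100000000005, 0.01), 2, 2)
  d <- mvmr_dataset(eb, es, rep(.1, 3), rep(.05, 3), list(S_ok, S_ok, S_ok))
  lam <- sapply(d$snp_cov, function(S) min(eigen(S, symmetric = TRUE)$values))
  expect_true(all(lam >= 0))
  # clearly indefinite: off-diagonal exceeds the diagonal
  S_bad <- matrix(c(0.01, 0.02, 0.02, 0.01), 2, 2)
  expect_error(
    mvmr_dataset(eb, es, rep(.1, 3), rep(.05, 3), list(S_bad, S_bad, S_bad)),
    "positive semi-definite")
})

test_that("validate reports violations without erroring", {
  d <- toy_dataset(L = 10)
  d_bad <- unclass(d)
  d_bad$outcome_se[3] <- -0.01
  v <- validate_mvmr_dataset(d_bad)
  expect_true(any(grepl("outcome_se", v) & grepl("snp_3", v)))

  d_bad2 <- unclass(d)
  d_bad2$snp_cov[[2]][1, 1] <- d_bad2$snp_cov[[2]][1, 1] * 2
  v2 <- validate_mvmr_dataset(d_bad2)
  expect_true(any(grepl("max relative discrepancy", v2)))
  expect_true(any(grepl("snp_2", v2)))
})

test_that("write-then-read round trip is bit-identical", {
  set.seed(3)
  d <- sim_dataset(n = 800, L = 25, seed = 3)$dataset
  ef <- tempfile(fileext = ".tsv"); of <- tempfile(fileext = ".tsv")
  cf <- tempfile(fileext = ".tsv")
  write_mvmr_summary(d, ef, of, cf)
  d2 <- read_mvmr_summary(ef, of, cov_source = cf)
  expect_identical(d2$snp_ids, d$snp_ids)
  expect_identical(d2$exposure_beta, d$exposure_beta)
  expect_identical(d2$exposure_se, d$exposure_se)
  expect_identical(d2$outcome_beta, d$outcome_beta)
  expect_identical(d2$outcome_se, d$outcome_se)
  for (j in seq_len(d$L)) {
    expect_equal(unname(d2$snp_cov[[j]]), unname(d$snp_cov[[j]]),
                 tolerance = 0)
  }
})

test_that("tables are intersected on SNP id with a logged drop count", {
  ex <- data.frame(SNP = paste0("rs", 1:5),
                   x1_beta = runif(5, .1, .2), x1_se = rep(.05, 5),
                   x2_beta = runif(5, .1, .2), x2_se = rep(.05, 5))
  out <- data.frame(SNP = paste0("rs", c(2, 4, 1, 3)),
                    beta = runif(4), se = rep(.04, 4))
  ef <- tempfile(); of <- tempfile()
  write.table(ex, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out, of, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(
    suppressWarnings(d <- read_mvmr_summary(ef, of, "zero")),
    "dropped 1 SNP")
  expect_equal(d$L, 4L)
  # order follows the exposure file, not the outcome file
  expect_identical(d$snp_ids, paste0("rs", 1:4))
  expect_equal(d$outcome_beta, out$beta[match(paste0("rs", 1:4), out$SNP)])
})

test_that("row order of inputs does not change any downstream statistic", {
  set.seed(11)
  rep <- sim_dataset(n = 800, L = 30, seed = 11)
  d <- rep$dataset
  perm <- sample(d$L)
  d_perm <- subset_mvmr(d, snps = perm)
  expect_identical(d_perm$snp_ids, d$snp_ids[perm])
  expect_equal(mvmr_ivw(d_perm)$beta, mvmr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(q_ivw(d_perm)$value, q_ivw(d)$value, tolerance = 1e-12)
  expect_equal(mvmr_strength(d_perm)$f_ts, mvmr_strength(d)$f_ts,
               tolerance = 1e-10)
})

test_that("the zero-covariance route carries a prominent warning", {
  ex <- data.frame(SNP = paste0("rs", 1:5),
                   x1_beta = runif(5, .1, .2), x1_se = rep(.05, 5),
                   x2_beta = runif(5, .1, .2), x2_se = rep(.05, 5))
  out <- data.frame(SNP = paste0("rs", 1:5), beta = runif(5), se = rep(.04, 5))
  ef <- tempfile(); of <- tempfile()
  write.table(ex, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out, of, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_mvmr_summary(ef, of, "zero"), "conditional F")
})

test_that("too few shared SNPs is a hard error naming the counts", {
  ex <- data.frame(SNP = paste0("rs", 1:4),
                   x1_beta = runif(4), x1_se = rep(.05, 4),
                   x2_beta = runif(4), x2_se = rep(.05, 4))
  out <- data.frame(SNP = c("rs1", "rs9", "rs8", "rs7"),
                    beta = runif(4), se = rep(.04, 4))
  ef <- tempfile(); of <- tempfile()
  write.table(ex, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out, of, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(suppressWarnings(
    read_mvmr_summary(ef, of, "zero"))), "1 usable SNP")
})
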