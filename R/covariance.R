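#' Per-SNP covariance of SNP-exposure estimation errors from individual data
#'
#' Computes, for every SNP j, the K x K covariance matrix of the estimation
#' errors of the univariable (single-SNP, with intercept) regressions of each
#' exposure on that SNP, from the individual-level data used to estimate the
#' associations:
#' \deqn{\sigma_{km,j} = (G_j'G_j)^{-1} \frac{1}{n}\sum_i \hat v_{ki}\hat v_{mi}}
#' where \eqn{\hat v_{ki}} is the residual of the regression of exposure k on
#' SNP j.  \eqn{G_j'G_j} is taken in mean-centered form, as in the standard
#' with-intercept regression.  The diagonal equals the squared standard error
#' of that regression under the same variance convention.
#'
#' @param genotypes n x L numeric matrix of genotype dosages (no missing
#'   values; monomorphic SNPs are an error).
#' @param exposures n x K numeric matrix of exposure phenotypes.
#' @param df_adjust residual-variance convention: `"n"` (divide the residual
#'   sum of squares by n, the default) or `"n-2"` (the usual unbiased OLS
#'   convention, which some GWAS software reports).
#' @return list of L symmetric K x K matrices.
#' @seealso [snpcov_phenocorr()], [snpcov_zero()]
#' @export
snpcov_individual <- function(genotypes, exposures, df_adjust = c("n", "n-2")) {
  df_adjust <- match.arg(df_adjust)
  G <- as.matrix(genotypes)
  X <- as.matrix(exposures)
  n <- nrow(G)
  L <- ncol(G)
  K <- ncol(X)
  if (nrow(X) != n) stop("genotypes and exposures must have the same rows")
  if (anyNA(G) || anyNA(X)) stop("missing values are not supported")
  if (n <= K + 1L) stop("need n > K + 1 individuals")

  Gc <- sweep(G, 2, colMeans(G))
  Xc <- sweep(X, 2, colMeans(X))
  sgg <- colSums(Gc^2)                      # per-SNP centered G'G
  mono <- which(sgg <= 0)
  if (length(mono)) {
    stop("monomorphic SNP (zero genotype variance) at column ",
         mono[1], call. = FALSE)
  }
  denom <- if (df_adjust == "n") n else n - 2L

  # slopes b[j, k]; residual cross-products via closed forms, avoiding an
  # explicit n x L residual matrix per exposure pair
  sgx <- crossprod(Gc, Xc)                  # L x K
  b <- sgx / sgg
  sxx <- crossprod(Xc)                      # K x K
  lapply(seq_len(L), function(j) {
    # sum_i v_ki v_mi = Sxx[k,m] - b_jk b_jm sgg_j
    rss <- sxx - tcrossprod(b[j, ]) * sgg[j]
    S <- rss / denom / sgg[j]
    (S + t(S)) / 2
  })
}

#' Per-SNP covariance matrices from a phenotypic correlation matrix
#'
#' Approximates the covariance between the estimation errors of SNP j's
#' associations with exposures k and m as
#' \eqn{\sigma_{km,j} = \rho_{km}\,\sigma_{k,j}\,\sigma_{m,j}},
#' where \eqn{\rho_{km}} is the (Pearson) phenotypic correlation between the
#' two exposures and \eqn{\sigma_{k,j}} the reported standard errors.  The
#' approximation is accurate when each SNP explains a small share of each
#' exposure's variance, and each output matrix is PSD whenever `rho` is
#' (it equals `D rho D` with `D` diagonal).
#'
#' @param rho K x K phenotypic correlation matrix: symmetric, unit diagonal,
#'   entries in \eqn{[-1, 1]}, positive semi-definite.
#' @param exposure_se L x K matrix of SNP-exposure standard errors.
#' @return list of L symmetric K x K matrices.
#' @export
snpcov_phenocorr <- function(rho, exposure_se) {
  rho <- as.matrix(rho)
  S <- as.matrix(exposure_se)
  K <- ncol(S)
  if (!identical(dim(rho), c(K, K))) stop("rho must be K x K with K = ", K)
  if (max(abs(rho - t(rho))) > 1e-8) stop("rho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8) stop("rho must have unit diagonal")
  if (any(abs(rho) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  lam <- eigen((rho + t(rho)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8 * max(abs(lam))) {
    stop("rho is not positive semi-definite")
  }
  rho <- (rho + t(rho)) / 2
  lapply(seq_len(nrow(S)), function(j) {
    rho * tcrossprod(S[j, ])
  })
}

#' Diagonal (zero-covariance) per-SNP covariance matrices
#'
#' The route for SNP-exposure associations estimated in mutually independent
#' samples: error covariances between exposures are zero and each matrix is
#' `diag(se^2)`.  Using this route when the associations actually come from
#' one sample invalidates the conditional F-statistic and beta_Q,het under
#' correlated SNP effects.
#'
#' @param exposure_se L x K matrix of SNP-exposure standard errors.
#' @return list of L diagonal K x K matrices.
#' @export
snpcov_zero <- function(exposure_se) {
  S <- as.matrix(exposure_se)
  K <- ncol(S)
  lapply(seq_len(nrow(S)), function(j) diag(S[j, ]^2, nrow = K))
}

#' Sensitivity of F_TS and beta_Q,het to the phenotypic correlation
#'
#' When the phenotypic correlation is estimated from data that do not match
#' the GWAS sample, the conditional F-statistic and the pleiotropy-robust
#' estimate should be recomputed across the plausible range of correlation
#' values.  This helper rebuilds the per-SNP covariances for each candidate
#' correlation matrix and re-runs both statistics.
#'
#' @param dataset an [mvmr_dataset()] with `K >= 2` exposures.
#' @param rho_grid list of K x K correlation matrices (or, for `K = 2`, a
#'   numeric vector of off-diagonal correlations).
#' @return data.frame with one row per grid point: the off-diagonal
#'   correlations, `fts_<exposure>` columns and `beta_qhet_<exposure>`
#'   columns.  Deterministic given the dataset and grid.
#' @export
rho_sensitivity <- function(dataset, rho_grid) {
  if (dataset$K < 2) {
    stop("rho sensitivity needs at least two exposures (K >= 2)")
  }
  if (is.numeric(rho_grid) && !is.list(rho_grid)) {
    if (dataset$K != 2) {
      stop("a numeric rho_grid is only supported for K = 2; supply matrices")
    }
    rho_grid <- lapply(rho_grid, function(r) matrix(c(1, r, r, 1), 2, 2))
  }
  if (length(rho_grid) == 0) stop("rho_grid must be nonempty")

  K <- dataset$K
  pair_idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  pair_names <- paste0("rho_", pair_idx[, 1], pair_idx[, 2])
  rows <- lapply(rho_grid, function(rho) {
    d <- mvmr_dataset(dataset$exposure_beta, dataset$exposure_se,
                      dataset$outcome_beta, dataset$outcome_se,
                      snpcov_phenocorr(rho, dataset$exposure_se),
                      snp_ids = dataset$snp_ids,
                      exposure_names = dataset$exposure_names)
    st <- mvmr_strength(d)
    qh <- suppressWarnings(mvmr_qhet(d))
    out <- c(as.matrix(rho)[pair_idx], st$f_ts, qh$beta)
    names(out) <- c(pair_names,
                    paste0("fts_", dataset$exposure_names),
                    paste0("beta_qhet_", dataset$exposure_names))
    out
  })
  as.data.frame(do.call(rbind, rows))
}
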