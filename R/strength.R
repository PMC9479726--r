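# Stock-Yogo-type critical values for the conditional weak-instrument test,
# indexed by number of instruments and tolerated relative bias of the IV
# estimator (squared-bias measure, exposures standardized).
.cf_critical_table <- matrix(
  c(21.37, 11.44, 6.19,
    21.26, 11.14, 5.86,
    21.02, 10.84, 5.64,
    20.79, 10.61, 5.46,
    20.62, 10.52, 5.38,
    20.56, 10.45, 5.32,
    20.50, 10.40, 5.29),
  ncol = 3, byrow = TRUE,
  dimnames = list(c("25", "50", "100", "200", "300", "400", "500"),
                  c("5%", "10%", "20%")))

#' Critical value for the conditional weak-instrument test
#'
#' Looks up the critical value against which the two-sample conditional
#' F-statistic is compared, for a null hypothesis that the relative bias of
#' the IV estimator (relative to OLS, squared-bias measure) is at least the
#' given level.  Values are linearly interpolated in the number of
#' instruments over the tabulated grid \{25, 50, 100, 200, 300, 400, 500\};
#' above 500 instruments the 500-row value is returned.  The table is not
#' validated below 25 instruments, where the common F > 10 rule of thumb has
#' no support either.
#'
#' @param n_instruments integer number of SNPs (>= 25).
#' @param relative_bias one of `"5%"`, `"10%"`, `"20%"` (or 0.05, 0.1, 0.2).
#' @return scalar critical value.
#' @export
#' @examples
#' cf_critical_value(100, "10%")  # 10.84
#' cf_critical_value(150, "20%")  # midpoint of 5.64 and 5.46
cf_critical_value <- function(n_instruments, relative_bias = "10%") {
  if (is.numeric(relative_bias)) {
    relative_bias <- sprintf("%g%%", 100 * relative_bias)
  }
  if (!relative_bias %in% colnames(.cf_critical_table)) {
    stop("relative_bias must be one of 5%, 10%, 20%")
  }
  if (n_instruments < 25) {
    stop("critical values are tabulated for 25 or more instruments; with ",
         n_instruments, " instruments neither this test nor the F > 10 rule ",
         "of thumb is validated", call. = FALSE)
  }
  grid <- as.numeric(rownames(.cf_critical_table))
  vals <- .cf_critical_table[, relative_bias]
  if (n_instruments >= max(grid)) return(unname(vals[length(vals)]))
  stats::approx(grid, vals, xout = n_instruments)$y
}

# delta* vector: -1 at position k, delta elsewhere (sign convention: the -1
# coefficient multiplies the exposure under test).
.delta_star <- function(delta, k, K) {
  ds <- numeric(K)
  ds[k] <- -1
  ds[-k] <- delta
  ds
}

# Per-SNP weight variances sigma^2_xk,j = delta*' Sigma_V,j delta*
.sigma2_xk <- function(snp_cov, dstar) {
  vapply(snp_cov, function(S) drop(crossprod(dstar, S %*% dstar)), 0)
}

#' Conditional-fit coefficients for one exposure
#'
#' Estimates the (K-1)-vector of coefficients from the inverse-variance
#' weighted, no-intercept regression of exposure k's SNP associations on the
#' other exposures' SNP associations.  The weights
#' \eqn{1/\sigma^2_{xk,j}} with
#' \eqn{\sigma^2_{xk,j} = \tilde\delta^{*\prime}\Sigma_{V,j}\tilde\delta^*}
#' themselves depend on the coefficients, so the weighted fit is iterated to
#' a fixed point (weights from the current coefficients, refit, repeat),
#' initialized at the unweighted least-squares solution.
#'
#' @param dataset an [mvmr_dataset()] with `K >= 2`.
#' @param k exposure under test (index or name).
#' @param tol convergence tolerance on `max(abs(delta_change))`.
#' @param max_iter iteration cap.
#' @return list with `delta` ((K-1)-vector, named by the conditioning
#'   exposures), `sigma2` (length-L weight variances at the fixed point),
#'   `iterations`, `converged`.
#' @export
conditional_delta <- function(dataset, k, tol = 1e-8, max_iter = 100L) {
  K <- dataset$K
  if (K < 2) stop("the conditional fit needs at least two exposures (K >= 2)")
  if (is.character(k)) k <- match(k, dataset$exposure_names)
  if (is.na(k) || k < 1 || k > K) stop("unknown exposure index")

  y <- dataset$exposure_beta[, k]
  X <- dataset$exposure_beta[, -k, drop = FALSE]
  others <- dataset$exposure_names[-k]

  fit_wls <- function(w) {
    sw <- sqrt(w)
    qr_x <- qr(X * sw)
    if (qr_x$rank < ncol(X)) {
      stop("collinear SNP-exposure associations among exposures ",
           paste(others, collapse = ", "), "; weighted design is singular",
           call. = FALSE)
    }
    drop(qr.coef(qr_x, y * sw))
  }

  delta <- fit_wls(rep(1, dataset$L))
  converged <- FALSE
  it <- 0L
  sigma2 <- NULL
  while (it < max_iter) {
    it <- it + 1L
    dstar <- .delta_star(delta, k, K)
    sigma2 <- .sigma2_xk(dataset$snp_cov, dstar)
    if (any(sigma2 <= 0)) {
      stop("nonpositive weight variance sigma^2_xk,j at SNP '",
           dataset$snp_ids[which(sigma2 <= 0)[1]],
           "'; the per-SNP covariance input is invalid", call. = FALSE)
    }
    delta_new <- fit_wls(1 / sigma2)
    step <- max(abs(delta_new - delta))
    delta <- delta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("conditional-fit weight iteration did not converge in ", max_iter,
         " iterations (last max step ", format(step, digits = 3),
         "); last iterate: ", paste(format(delta, digits = 6), collapse = ", "),
         call. = FALSE)
  }
  dstar <- .delta_star(delta, k, K)
  sigma2 <- .sigma2_xk(dataset$snp_cov, dstar)
  names(delta) <- others
  list(delta = delta, sigma2 = sigma2, iterations = it, converged = TRUE)
}

#' Conditional instrument-strength Q statistic for one exposure
#'
#' Computes \eqn{Q_{xk} = \sum_j (\hat\pi_{kj} -
#' \tilde\delta'\hat\Pi_{-k,j})^2/\sigma^2_{xk,j}} at the fixed point of
#' [conditional_delta()].  Under the null that the instruments cannot
#' predict exposure k conditional on the other exposures, \eqn{Q_{xk}} is
#' asymptotically chi-squared with L - 1 degrees of freedom (the
#' underidentification test); the weak-instrument comparison divides by
#' L - (K - 1) instead (see [conditional_F()]).
#'
#' @inheritParams conditional_delta
#' @return list with `q_x`, `dof_underid` (= L - 1), `p_underid`, `delta`,
#'   `sigma2`, `per_snp` (per-SNP contributions).
#' @export
q_exposure <- function(dataset, k) {
  if (is.character(k)) k <- match(k, dataset$exposure_names)
  cd <- conditional_delta(dataset, k)
  y <- dataset$exposure_beta[, k]
  X <- dataset$exposure_beta[, -k, drop = FALSE]
  resid <- y - drop(X %*% cd$delta)
  per_snp <- resid^2 / cd$sigma2
  q <- sum(per_snp)
  list(q_x = q, dof_underid = dataset$L - 1L,
       p_underid = stats::pchisq(q, df = dataset$L - 1L, lower.tail = FALSE),
       delta = cd$delta, sigma2 = cd$sigma2, per_snp = per_snp)
}

#' Two-sample conditional F-statistic for one exposure
#'
#' \eqn{F_{TS,k} = Q_{xk} / (L - (K - 1))}: the summary-data analogue of the
#' individual-level conditional F-statistic, measuring how strongly the
#' instruments predict exposure k conditional on the other exposures.
#' Compared against the tabulated critical values to test the null that the
#' relative bias of the IV estimator exceeds 5%, 10% or 20%; rejecting means
#' the instruments are strong enough at that bias level.
#'
#' @inheritParams conditional_delta
#' @param bias_levels which critical-value columns to report verdicts for.
#' @return object of class `mvmr_strength_result`: list with `exposure`,
#'   `q_x`, `f_ts`, `dof` (= L - K + 1), `dof_underid`, `p_underid`,
#'   `delta`, `verdicts` (named character vector, `"reject"` = instruments
#'   strong at that relative-bias level).  Verdicts are `NA` when fewer than
#'   25 instruments are available.
#' @export
conditional_F <- function(dataset, k, bias_levels = c("5%", "10%", "20%")) {
  if (is.character(k)) k <- match(k, dataset$exposure_names)
  L <- dataset$L; K <- dataset$K
  dof <- L - (K - 1L)
  if (dof < 1) stop("L must exceed K - 1 instruments")
  qe <- q_exposure(dataset, k)
  f_ts <- qe$q_x / dof
  verdicts <- vapply(bias_levels, function(b) {
    if (L < 25) return(NA_character_)
    if (f_ts > cf_critical_value(L, b)) "reject" else "fail-to-reject"
  }, "")
  structure(
    list(exposure = dataset$exposure_names[k], q_x = qe$q_x, f_ts = f_ts,
         dof = dof, dof_underid = qe$dof_underid, p_underid = qe$p_underid,
         delta = qe$delta, verdicts = verdicts),
    class = "mvmr_strength_result")
}

#' @export
print.mvmr_strength_result <- function(x, ...) {
  cat(sprintf("Conditional strength for '%s': Q_x = %.3f, F_TS = %.3f (dof %d)\n",
              x$exposure, x$q_x, x$f_ts, x$dof))
  cat(sprintf("  underidentification: chi2_%d p = %.3g\n",
              x$dof_underid, x$p_underid))
  for (b in names(x$verdicts)) {
    cat(sprintf("  relative bias %s: %s\n", b, x$verdicts[b]))
  }
  invisible(x)
}

#' Conditional instrument-strength table for all exposures
#'
#' Runs [conditional_F()] for every exposure and returns a per-exposure
#' table, the first diagnostic of the MVMR workflow.
#'
#' @param dataset an [mvmr_dataset()] with `K >= 2`.
#' @param bias_level relative-bias level used for the `verdict` column.
#' @return data.frame with columns `exposure`, `q_x`, `dof`, `f_ts`,
#'   `p_underid`, `verdict`.
#' @export
mvmr_strength <- function(dataset, bias_level = "10%") {
  rows <- lapply(seq_len(dataset$K), function(k) {
    cf <- conditional_F(dataset, k, bias_levels = bias_level)
    data.frame(exposure = cf$exposure, q_x = cf$q_x, dof = cf$dof,
               f_ts = cf$f_ts, p_underid = cf$p_underid,
               verdict = unname(cf$verdicts[1]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
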