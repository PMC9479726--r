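# Precomputed pieces shared by all Q-statistic code paths.
# Sb columns let beta -> Sigma_j beta be a single matrix product per exposure.
.qa_parts <- function(dataset) {
  K <- dataset$K
  P <- dataset$exposure_beta
  covs <- dataset$snp_cov
  Cslices <- lapply(seq_len(K), function(a) {
    # L x K matrix whose row j is Sigma_j[a, ]
    matrix(vapply(covs, function(S) S[a, ], numeric(K)), ncol = K,
           byrow = TRUE)
  })
  list(P = P, G = dataset$outcome_beta, sy2 = dataset$outcome_se^2,
       Cslices = Cslices, L = dataset$L, K = K, snp_ids = dataset$snp_ids)
}

# Sigma_j beta for all j at once: L x K matrix
.sigma_beta <- function(parts, beta) {
  out <- vapply(parts$Cslices, function(Ca) drop(Ca %*% beta),
                numeric(parts$L))
  matrix(out, nrow = parts$L)
}

.qa_value <- function(parts, beta, tau2 = 0) {
  r <- parts$G - drop(parts$P %*% beta)
  qf <- drop(.sigma_beta(parts, beta) %*% beta)
  per_snp <- r^2 / (parts$sy2 + qf + tau2)
  list(value = sum(per_snp), per_snp = per_snp)
}

.qa_grad <- function(parts, beta, tau2 = 0) {
  r <- parts$G - drop(parts$P %*% beta)
  Sb <- .sigma_beta(parts, beta)
  w <- parts$sy2 + drop(Sb %*% beta) + tau2
  drop(-2 * crossprod(parts$P, r / w) - 2 * crossprod(Sb, r^2 / w^2))
}

# Multistart minimization of Q_A(beta, tau2) over beta.  The objective is
# non-convex (the weights depend on beta), so we refine a derivative-free
# simplex solution with quasi-Newton from several deterministic starts.
.qa_min <- function(parts, tau2 = 0, starts, reltol = 1e-12) {
  fn <- function(b) .qa_value(parts, b, tau2)$value
  gr <- function(b) .qa_grad(parts, b, tau2)
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    s <- as.numeric(s)
    res <- if (parts$K >= 2) {
      nm <- stats::optim(s, fn, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = 2000))
      stats::optim(nm$par, fn, gr, method = "BFGS",
                   control = list(reltol = reltol, maxit = 500))
    } else {
      stats::optim(s, fn, gr, method = "BFGS",
                   control = list(reltol = reltol, maxit = 500))
    }
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(beta = best$par, value = best$value, converged = any_conv)
}

.default_starts <- function(beta_ivw) {
  list(beta_ivw, rep(0, length(beta_ivw)), 1.5 * beta_ivw, 0.5 * beta_ivw)
}

.new_het <- function(statistic, value, per_snp, dof, beta, tau2 = 0,
                     snp_ids = NULL) {
  if (!is.null(snp_ids)) names(per_snp) <- snp_ids
  structure(list(statistic = statistic, value = value, dof = dof,
                 p_value = stats::pchisq(value, df = dof, lower.tail = FALSE),
                 per_snp = per_snp, beta_at_min = beta, tau2 = tau2),
            class = "mvmr_het")
}

#' @export
print.mvmr_het <- function(x, ...) {
  cat(sprintf("%s = %.3f on %d dof, p = %.3g\n",
              x$statistic, x$value, x$dof, x$p_value))
  invisible(x)
}

.new_estimate <- function(method, beta, se = rep(NA_real_, length(beta)),
                          tau2 = NULL, converged = TRUE, n_snps = NA_integer_,
                          exposure_names = NULL) {
  if (!is.null(exposure_names)) names(beta) <- names(se) <- exposure_names
  structure(list(method = method, beta = beta, se = se, tau2 = tau2,
                 converged = converged, n_snps_used = n_snps),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("MVMR estimate (%s), %d SNPs%s\n", x$method, x$n_snps_used,
              if (!is.null(x$tau2)) sprintf(", tau2 = %.4g", x$tau2) else ""))
  tab <- data.frame(beta = x$beta, se = x$se,
                    ci_low = x$beta - stats::qnorm(0.975) * x$se,
                    ci_high = x$beta + stats::qnorm(0.975) * x$se)
  print(tab, digits = 4)
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  invisible(x)
}

#' Multivariable IVW estimate
#'
#' Standard inverse-variance weighted MVMR: weighted least squares of the
#' SNP-outcome associations on the K SNP-exposure associations, no intercept,
#' weights \eqn{1/\sigma^2_{y,j}}.  This estimator implicitly assumes the
#' residual variance per SNP is \eqn{\sigma^2_{y,j}} alone, ignoring the
#' contribution of the SNP-exposure estimation error, and is therefore biased
#' when instruments are conditionally weak.
#'
#' @param dataset an [mvmr_dataset()].
#' @param overdispersion if `TRUE`, inflate the analytic variance by
#'   `max(1, Q_IVW / (L - K))`.  Off by default: the package's robust path is
#'   beta_Q,het with jackknife intervals, not inflated IVW.
#' @return an object of class `mvmr_estimate` (method `"IVW"`).
#' @export
mvmr_ivw <- function(dataset, overdispersion = FALSE) {
  P <- dataset$exposure_beta
  w <- 1 / dataset$outcome_se^2
  sw <- sqrt(w)
  qr_x <- qr(P * sw)
  if (qr_x$rank < ncol(P)) {
    stop("singular weighted design: exposure associations are collinear",
         call. = FALSE)
  }
  beta <- drop(qr.coef(qr_x, dataset$outcome_beta * sw))
  XtWX_inv <- chol2inv(qr.R(qr_x))
  vr <- diag(XtWX_inv)
  if (overdispersion) {
    q <- sum(w * (dataset$outcome_beta - drop(P %*% beta))^2)
    vr <- vr * max(1, q / (dataset$L - dataset$K))
  }
  .new_estimate("IVW", beta, sqrt(vr), n_snps = dataset$L,
                exposure_names = dataset$exposure_names)
}

#' Q_A heterogeneity statistic at a given effect vector
#'
#' Evaluates \eqn{Q_A(\beta, \tau^2) = \sum_j (\hat\Gamma_j -
#' \beta'\hat\pi_j)^2 / (\sigma^2_{y,j} + \beta'\Sigma_{V,j}\beta + \tau^2)},
#' the heterogeneity statistic whose weights account for the SNP-exposure
#' estimation error (and optionally a pleiotropy variance \eqn{\tau^2}).
#'
#' @param dataset an [mvmr_dataset()].
#' @param beta length-K effect vector at which to evaluate.
#' @param tau2 nonnegative pleiotropy variance added to every weight.
#' @return an object of class `mvmr_het` with per-SNP contributions; the
#'   p-value refers to the chi-squared distribution with L - K dof, which is
#'   exact for the *minimized* statistic.
#' @export
q_a <- function(dataset, beta, tau2 = 0) {
  stopifnot(length(beta) == dataset$K, tau2 >= 0)
  parts <- .qa_parts(dataset)
  qa <- .qa_value(parts, beta, tau2)
  .new_het("Q_A", qa$value, qa$per_snp, dataset$L - dataset$K, beta, tau2,
           dataset$snp_ids)
}

#' Standard MVMR heterogeneity statistic Q_IVW
#'
#' The Q statistic evaluated at the IVW estimate with weights
#' \eqn{1/\sigma^2_{y,j}} only.  Over-rejects the no-pleiotropy null in the
#' presence of weak instruments because it ignores the
#' \eqn{\beta'\Sigma_{V,j}\beta} variance component.
#'
#' @param dataset an [mvmr_dataset()].
#' @return an object of class `mvmr_het`.
#' @export
q_ivw <- function(dataset) {
  est <- mvmr_ivw(dataset)
  r <- dataset$outcome_beta - drop(dataset$exposure_beta %*% est$beta)
  per_snp <- r^2 / dataset$outcome_se^2
  .new_het("Q_IVW", sum(per_snp), per_snp, dataset$L - dataset$K, est$beta,
           snp_ids = dataset$snp_ids)
}

#' Iteratively updated heterogeneity statistic Q_IVW,up
#'
#' Fixed-point alternative between Q_IVW and the fully minimized Q_A: starting
#' from the IVW estimate, the weights are extended to
#' \eqn{1/(\sigma^2_{y,j} + \beta'\Sigma_{V,j}\beta)}, the weighted
#' least-squares estimate is re-solved, and the two steps are iterated to
#' convergence.  The statistic is the final weighted residual sum of squares.
#' It reduces the over-rejection of Q_IVW under weak instruments without
#' fully correcting it.
#'
#' @param dataset an [mvmr_dataset()].
#' @param tol convergence tolerance on `max(abs(beta_change))`.
#' @param max_iter iteration cap.
#' @return an object of class `mvmr_het`.
#' @export
q_ivw_updated <- function(dataset, tol = 1e-8, max_iter = 100L) {
  parts <- .qa_parts(dataset)
  P <- parts$P
  beta <- mvmr_ivw(dataset)$beta
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    w <- 1 / (parts$sy2 + drop(.sigma_beta(parts, beta) %*% beta))
    sw <- sqrt(w)
    qr_x <- qr(P * sw)
    if (qr_x$rank < ncol(P)) stop("singular weighted design", call. = FALSE)
    beta_new <- drop(qr.coef(qr_x, parts$G * sw))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("weight/estimate iteration did not converge in ", max_iter,
         " iterations; last iterate: ",
         paste(format(beta, digits = 6), collapse = ", "), call. = FALSE)
  }
  qa <- .qa_value(parts, beta, 0)
  .new_het("Q_IVW_up", qa$value, qa$per_snp, dataset$L - dataset$K, beta,
           snp_ids = dataset$snp_ids)
}

#' Weak-instrument robust estimation by Q_A minimization
#'
#' Estimates the direct causal effects as the minimizer of
#' \eqn{Q_A(\beta, \tau^2 = 0)}.  The minimized statistic provides an exact
#' chi-squared (L - K dof) test for pleiotropy even under weak instruments.
#' The estimate itself is robust to weak instruments but not to pleiotropy;
#' under severe conditional weakness the minimizing beta can run far from the
#' plausible range (the objective flattens), which is flagged as an
#' instability warning rather than an error.
#'
#' @param dataset an [mvmr_dataset()].
#' @param se how to compute standard errors: `"none"` (default; use
#'   [jackknife_se()] for intervals) or `"jackknife"`.
#' @return list with elements `estimate` (an `mvmr_estimate`, method `"Q"`)
#'   and `heterogeneity` (an `mvmr_het` for the minimized Q_A).
#' @export
mvmr_q <- function(dataset, se = c("none", "jackknife")) {
  se <- match.arg(se)
  parts <- .qa_parts(dataset)
  ivw <- mvmr_ivw(dataset)$beta
  opt <- .qa_min(parts, 0, .default_starts(ivw))
  if (!opt$converged) {
    stop("Q_A minimization did not converge from any start; best iterate: ",
         paste(format(opt$beta, digits = 6), collapse = ", "), call. = FALSE)
  }
  if (any(abs(opt$beta) > 100 * pmax(abs(ivw), 1e-8))) {
    warning("beta_Q is far outside the IVW scale; the instruments are ",
            "likely too weak for a stable point estimate", call. = FALSE)
  }
  qa <- .qa_value(parts, opt$beta, 0)
  est <- .new_estimate("Q", opt$beta, n_snps = dataset$L,
                       exposure_names = dataset$exposure_names)
  if (se == "jackknife") est$se <- jackknife_se(dataset, "Q")
  list(estimate = est,
       heterogeneity = .new_het("Q_A", qa$value, qa$per_snp,
                                dataset$L - dataset$K, opt$beta,
                                snp_ids = dataset$snp_ids))
}

#' Weak-instrument and pleiotropy robust estimation (beta_Q,het)
#'
#' Solves the simultaneous system in \eqn{(\beta, \tau^2)}: \eqn{\beta}
#' minimizes \eqn{Q_A(\cdot, \tau^2)} (gradient condition) and the minimized
#' statistic equals its expectation \eqn{L - K} under homogeneity (moment
#' condition), so the pleiotropy variance \eqn{\tau^2} absorbs the excess
#' heterogeneity.  Solved as an outer scalar root-find on \eqn{\tau^2} of
#' \eqn{g(\tau^2) = \min_\beta Q_A(\beta, \tau^2) - (L - K)} with an inner
#' warm-started minimization; \eqn{g} is strictly decreasing whenever the
#' residuals are nonzero, so the root is unique.  If \eqn{Q_{A,min} \le L-K}
#' already at \eqn{\tau^2 = 0} the solution is truncated to
#' \eqn{\hat\tau^2 = 0} and \eqn{\hat\beta = \hat\beta_Q}.
#'
#' @param dataset an [mvmr_dataset()] with `L >= K + 2`.
#' @param se `"none"` (default) or `"jackknife"`.
#' @param tol absolute tolerance on the moment condition
#'   `|Q_A(beta, tau2) - (L - K)|`.
#' @return an object of class `mvmr_estimate` (method `"Q_het"`) carrying
#'   `tau2`; attribute `"heterogeneity"` holds the `mvmr_het` at the solution.
#' @export
mvmr_qhet <- function(dataset, se = c("none", "jackknife"), tol = 1e-8) {
  se <- match.arg(se)
  if (dataset$L < dataset$K + 2L) {
    stop("beta_Q,het needs L >= K + 2 SNPs", call. = FALSE)
  }
  parts <- .qa_parts(dataset)
  target <- dataset$L - dataset$K
  ivw <- mvmr_ivw(dataset)$beta

  opt0 <- .qa_min(parts, 0, .default_starts(ivw))
  if (opt0$value <= target) {
    est <- .new_estimate("Q_het", opt0$beta, tau2 = 0,
                         converged = opt0$converged, n_snps = dataset$L,
                         exposure_names = dataset$exposure_names)
    qa <- .qa_value(parts, opt0$beta, 0)
    attr(est, "heterogeneity") <- .new_het("Q_A", qa$value, qa$per_snp,
                                           target, opt0$beta, 0,
                                           dataset$snp_ids)
    if (se == "jackknife") est$se <- jackknife_se(dataset, "Q_het")
    return(est)
  }

  # bracket the root in tau2: grow geometrically from the IVW residual scale
  g_at <- function(tau2, start_beta) {
    opt <- .qa_min(parts, tau2, list(start_beta, ivw))
    list(g = opt$value - target, beta = opt$beta)
  }
  lo <- 0; g_lo <- opt0$value - target
  beta_cur <- opt0$beta
  hi <- max(stats::var(parts$G - drop(parts$P %*% ivw)), 1e-8)
  r <- g_at(hi, beta_cur)
  grow <- 0L
  while (r$g > 0) {
    grow <- grow + 1L
    if (grow > 60L) {
      stop("could not bracket tau2: Q_A,min - (L - K) is ",
           format(r$g, digits = 4), " at tau2 = ", format(hi, digits = 4),
           " and ", format(g_lo, digits = 4), " at tau2 = 0", call. = FALSE)
    }
    lo <- hi; g_lo <- r$g; beta_cur <- r$beta
    hi <- hi * 4
    r <- g_at(hi, beta_cur)
  }
  g_hi <- r$g; beta_hi <- r$beta

  # Newton on the moment condition with the envelope derivative
  # dQmin/dtau2 = -sum(r_j^2 / w_j^2) at the inner minimizer, safeguarded by
  # bisection inside the bracket.
  x <- (lo + hi) / 2
  beta_x <- if (abs(g_lo) < abs(g_hi)) beta_cur else beta_hi
  g_x <- NA_real_
  for (it in seq_len(100L)) {
    rx <- g_at(x, beta_x)
    g_x <- rx$g; beta_x <- rx$beta
    if (abs(g_x) < tol) break
    if (g_x > 0) { lo <- x; g_lo <- g_x } else { hi <- x; g_hi <- g_x }
    resid <- parts$G - drop(parts$P %*% beta_x)
    w <- parts$sy2 + drop(.sigma_beta(parts, beta_x) %*% beta_x) + x
    slope <- -sum(resid^2 / w^2)
    x_new <- x - g_x / slope
    x <- if (is.finite(x_new) && x_new > lo && x_new < hi) x_new else (lo + hi) / 2
  }
  if (abs(g_x) >= tol) {
    stop("tau2 root refinement stalled: |Q_A,min - (L - K)| = ",
         format(abs(g_x), digits = 4), call. = FALSE)
  }
  est <- .new_estimate("Q_het", beta_x, tau2 = x, converged = TRUE,
                       n_snps = dataset$L,
                       exposure_names = dataset$exposure_names)
  qa <- .qa_value(parts, beta_x, x)
  attr(est, "heterogeneity") <- .new_het("Q_A", qa$value, qa$per_snp, target,
                                         beta_x, x, dataset$snp_ids)
  if (se == "jackknife") est$se <- jackknife_se(dataset, "Q_het")
  est
}

#' Jackknife standard errors for the Q-based estimators
#'
#' Leave-one-SNP-out standard errors: the model is re-estimated L times, each
#' time excluding one SNP, and
#' \deqn{SE_k = \sqrt{\frac{L-1}{L}\sum_i (\hat\beta_{k,(-i)} -
#'   \bar\beta_k)^2}.}
#' Preferred over a bootstrap because resampling SNPs can produce very weak
#' instrument sets in individual draws even when the full set is adequate.
#'
#' @param dataset an [mvmr_dataset()] with `L >= K + 2` (so every
#'   leave-one-out fit retains positive degrees of freedom).
#' @param method `"Q"`, `"Q_het"` or `"IVW"`.
#' @return named length-K numeric vector of standard errors, with the L x K
#'   matrix of leave-one-out estimates attached as attribute `"replicates"`.
#' @export
jackknife_se <- function(dataset, method = c("Q", "Q_het", "IVW")) {
  method <- match.arg(method)
  L <- dataset$L
  if (L < dataset$K + 2L) {
    stop("jackknife needs L >= K + 2 SNPs so each leave-one-out model is ",
         "estimable", call. = FALSE)
  }
  fit_one <- function(d) {
    switch(method,
           Q = mvmr_q(d)$estimate$beta,
           Q_het = mvmr_qhet(d)$beta,
           IVW = mvmr_ivw(d)$beta)
  }
  reps <- matrix(NA_real_, L, dataset$K)
  for (i in seq_len(L)) {
    reps[i, ] <- tryCatch(
      suppressWarnings(fit_one(subset_mvmr(dataset, snps = -i))),
      error = function(e) {
        stop("leave-one-out fit failed when excluding SNP '",
             dataset$snp_ids[i], "': ", conditionMessage(e), call. = FALSE)
      })
  }
  se <- sqrt((L - 1) / L * colSums(sweep(reps, 2, colMeans(reps))^2))
  names(se) <- dataset$exposure_names
  attr(se, "replicates") <- reps
  se
}

#' Rank SNPs by their contribution to a heterogeneity statistic
#'
#' Large individual contributions to Q_A point at candidate pleiotropic
#' outliers; removing the top contributors and re-fitting is the standard
#' sensitivity analysis (left to the caller).
#'
#' @param het an `mvmr_het` object with populated per-SNP contributions.
#' @param top_n how many SNPs to return (default all).
#' @return data.frame with columns `rank`, `snp`, `contribution`, sorted by
#'   decreasing contribution; ties keep input order.
#' @export
outlier_snps <- function(het, top_n = length(het$per_snp)) {
  stopifnot(inherits(het, "mvmr_het"))
  ord <- order(-het$per_snp)   # stable: ties keep original positions
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(ord),
             snp = if (!is.null(names(het$per_snp))) names(het$per_snp)[ord] else ord,
             contribution = unname(het$per_snp[ord]),
             stringsAsFactors = FALSE)
}

#' All three heterogeneity tests plus outlier listing
#'
#' Convenience wrapper running [q_ivw()], [q_ivw_updated()] and the minimized
#' Q_A of [mvmr_q()] on one dataset and listing the largest per-SNP
#' contributors to Q_A.
#'
#' @param dataset an [mvmr_dataset()].
#' @param top_n number of outlier SNPs to list.
#' @return list with `q_ivw`, `q_ivw_up`, `q_a_min` (each `mvmr_het`) and
#'   `outliers` (data.frame).
#' @export
mvmr_pleiotropy <- function(dataset, top_n = 10L) {
  qa <- suppressWarnings(mvmr_q(dataset))$heterogeneity
  list(q_ivw = q_ivw(dataset), q_ivw_up = q_ivw_updated(dataset),
       q_a_min = qa, outliers = outlier_snps(qa, top_n))
}
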