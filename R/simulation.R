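# ---------------------------------------------------------------------------
# Monte-Carlo designs for two-sample MVMR.
#
# All designs share one data-generating process:
#   genotypes   G_ij ~ Binomial(2, f_j),   f_j ~ U(0.1, 0.9)
#   exposures   X_k  = sum_j pi_kj G_j + c_k U + e_k,  U, e_k ~ N(0, 1)
#   outcome     Y    = beta' X + sum_j alpha_j G_j + U + e_y,
#               alpha_j ~ N(0, tau2)  (balanced pleiotropy; 0 when tau2 = 0)
# with two independent samples per replicate (exposure sample and outcome
# sample) that share the same true effect matrix Pi and the same pleiotropic
# effects alpha.  Per-SNP effects are uniform draws, optionally loaded on a
# shared uniform component theta to induce correlation across exposures:
#   pi_kj = loading_k * theta_j + u_kj,  theta_j ~ U(0, theta_max),
#   u_kj ~ U(u_lo_k, u_hi_k).
#
# Effect ranges and the confounder loading are not free dials: they are
# solved at design construction from instrument-strength anchors (the mean
# univariable first-stage F and the mean conditional F_TS the scenario is
# defined by), using a closed-form second-moment model of the DGP.  See the
# methods vignette for the derivation.
# ---------------------------------------------------------------------------

.GBAR <- 59 / 150   # E[2 f (1 - f)] for f ~ U(0.1, 0.9): mean genotype variance

# Uniform moments for u ~ U(lo, hi)
.umean <- function(lo, hi) (lo + hi) / 2
.usq <- function(lo, hi) (lo^2 + lo * hi + hi^2) / 3

# Second-moment matrix T[k, m] = E[pi_k pi_m] of the per-SNP effects
.effects_T <- function(loading, theta_max, u_lo, u_hi) {
  K <- length(loading)
  Eth <- theta_max / 2
  Eth2 <- theta_max^2 / 3
  mu <- .umean(u_lo, u_hi)
  T <- outer(loading, loading) * Eth2 +
    outer(loading * Eth, mu) + outer(mu, loading * Eth) + outer(mu, mu)
  diag(T) <- loading^2 * Eth2 + 2 * loading * Eth * mu + .usq(u_lo, u_hi)
  T
}

# Phenotypic covariance of the exposures implied by a design
.sigma_x <- function(T, L, confounder, noise_x) {
  L * .GBAR * T + outer(confounder, confounder) + diag(noise_x^2,
                                                       nrow = nrow(T))
}

# Expected two-sample conditional F for exposure k under the moment model.
# delta is the probability limit of the IVW conditional fit (weights cancel
# as a scalar when Sigma_V,j is proportional across SNPs, which holds for
# the phenotypic-correlation route); the Sigma_X/n terms are the estimation-
# noise moments that attenuate the fit under weak instruments.
.model_fts <- function(T, sigma_x, n, L, k, zero_cov = FALSE) {
  K <- nrow(T)
  A <- .GBAR * T[-k, -k, drop = FALSE] + sigma_x[-k, -k, drop = FALSE] / n
  b <- .GBAR * T[-k, k] + sigma_x[-k, k] / n
  delta <- solve(A, b)
  dstar <- numeric(K); dstar[k] <- -1; dstar[-k] <- delta
  num_sig <- drop(crossprod(dstar, T %*% dstar))
  D_true <- drop(crossprod(dstar, sigma_x %*% dstar))
  D_w <- if (zero_cov) sum(dstar^2 * diag(sigma_x)) else D_true
  EQ <- (n * L * .GBAR * num_sig + L * D_true) / D_w
  EQ / (L - (K - 1))
}

# Expected univariable (all-SNP joint first-stage) F for exposure k
.model_f_marginal <- function(T, n, confounder, noise_x, k) {
  1 + n * .GBAR * T[k, k] / (confounder[k]^2 + noise_x^2)
}

# Probability limit of the IVW estimate under the moment model: the
# SNP-exposure estimation noise (second term) attenuates and mixes the true
# effects, which is exactly the weak-instrument bias of MVMR-IVW.
.model_ivw <- function(T, sigma_x, n, beta) {
  drop(solve(.GBAR * T + sigma_x / n, .GBAR * T %*% beta))
}

# T_kk value that yields a target marginal F
.tkk_for_f <- function(f_target, n, c, noise_x = 1) {
  (f_target - 1) * (c^2 + noise_x^2) / (n * .GBAR)
}

# Weak scenario: both exposures individually weak (mean univariable F ~8.8)
# and conditionally weak (mean F_TS ~3.35).  Effects u ~ U(shape*hi, hi);
# the support shape and the two confounder loadings are solved so the
# conditional strength and the IVW weak-instrument attenuation match their
# anchors, with the per-exposure effect scale nested to keep F on target.
.calibrate_weak <- function(n, L, f_target = 8.80, fts_target = 3.35,
                            ivw_target = c(0.352, -0.128),
                            beta = c(0.5, -0.3)) {
  build <- function(p) {
    shape <- 1 / (1 + exp(-p[1]))        # support ratio u_lo/u_hi in (0, 1)
    c1 <- exp(p[2]); c2 <- exp(p[3])
    hi <- vapply(c(c1, c2), function(cc) {
      sqrt(3 * .tkk_for_f(f_target, n, cc) / (1 + shape + shape^2))
    }, 0)
    list(confounder = c(c1, c2), theta_max = 0, loading = c(0, 0),
         u_lo = shape * hi, u_hi = hi)
  }
  obj <- function(p) {
    d <- build(p)
    T <- .effects_T(d$loading, d$theta_max, d$u_lo, d$u_hi)
    SX <- .sigma_x(T, L, d$confounder, 1)
    fts <- .model_fts(T, SX, n, L, 1)
    ivw <- .model_ivw(T, SX, n, beta)
    (log(fts - 1) - log(fts_target - 1))^2 + sum((ivw - ivw_target)^2)
  }
  start <- c(0, log(0.4), log(0.4))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-13))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-13))
  build(fit$par)
}

# Conditionally weak scenario: a shared strong component makes both
# exposures marginally very strong while the independent components are
# small, so conditional strength sits near F_TS ~9.1.  All anchors are
# imposed at the actual sample size, which makes the scenario scale-free.
.calibrate_condweak <- function(n, L, c = 1,
                                f_marg = c(1602.81, 3107.5),
                                fts_target = 9.13) {
  h <- 0
  Eth2 <- lam <- NA_real_
  for (pass in 1:6) {
    Eth2 <- .tkk_for_f(f_marg[1], n, c) - h^2 / 3
    lam <- sqrt((.tkk_for_f(f_marg[2], n, c) - h^2 / 3) / Eth2)
    gap <- function(hh) {
      T <- .effects_T(c(1, lam), sqrt(3 * Eth2), c(-hh, -hh), c(hh, hh))
      .model_fts(T, .sigma_x(T, L, rep(c, 2), 1), n, L, 1) - fts_target
    }
    hmax <- 0.99 * sqrt(3 * Eth2)
    h_new <- stats::uniroot(gap, c(1e-8, hmax), tol = 1e-12)$root
    if (abs(h_new - h) < 1e-10) { h <- h_new; break }
    h <- h_new
  }
  list(confounder = rep(c, 2), theta_max = sqrt(3 * Eth2),
       loading = c(1, lam), u_lo = c(-h, -h), u_hi = c(h, h))
}

# Three-exposure scenario.  The conditional anchors for the three-exposure
# fit do not by themselves pin down how much of exposure 1 and 3's strength
# is shared; the conditional F of the two-exposure fit (exposures 1 and 2
# only) does, so it enters the objective as a fourth target.
.calibrate_three <- function(n, L, c = 1,
                             f_marg = c(236.2, 235.13, 14.50),
                             fts_target = c(6.58, 17.94, 3.23),
                             fts2_target = 45.01) {
  tkk <- vapply(f_marg, .tkk_for_f, 0, n = n, c = c)
  build <- function(p) {
    h1 <- exp(p[1]); h3 <- exp(p[2]); shape2 <- exp(p[3])
    Eth2 <- tkk[1] - h1^2 / 3
    if (Eth2 <= 0) return(NULL)
    s2 <- (tkk[3] - h3^2 / 3) / Eth2
    if (s2 <= 0) return(NULL)
    m2 <- sqrt(tkk[2] / (1 + shape2^2 / 3))
    h2 <- shape2 * m2
    list(confounder = rep(c, 3), theta_max = sqrt(3 * Eth2),
         loading = c(1, 0, sqrt(s2)),
         u_lo = c(-h1, m2 - h2, -h3), u_hi = c(h1, m2 + h2, h3))
  }
  obj <- function(p) {
    d <- build(p)
    if (is.null(d)) return(1e6)
    T <- .effects_T(d$loading, d$theta_max, d$u_lo, d$u_hi)
    SX <- .sigma_x(T, L, d$confounder, 1)
    fts <- vapply(1:3, function(k) .model_fts(T, SX, n, L, k), 0)
    fts2 <- .model_fts(T[1:2, 1:2], SX[1:2, 1:2], n, L, 1)
    # the two-exposure anchor enters with a small weight: it identifies the
    # shared-vs-independent decomposition but is not exactly attainable
    # jointly with the three-exposure anchors in this effect family
    sum(c(1, 1, 1, 0.1) * (log(pmax(c(fts, fts2) - 1, 1e-8)) -
                             log(c(fts_target, fts2_target) - 1))^2)
  }
  starts <- list(
    log(c(0.1 * sqrt(3 * tkk[1]), 0.1 * sqrt(3 * tkk[3]), 0.4)),
    log(c(0.3, 0.02, 0.2)),
    log(c(0.15, 0.04, 1)))
  fit <- NULL
  for (start in starts) {
    cand <- stats::optim(start, obj, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-13))
    cand <- stats::optim(cand$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-13))
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  build(fit$par)
}

#' Define a simulation design for two-sample MVMR
#'
#' Resolves one of the named study scenarios into a fully parameterized
#' data-generating process:
#' \describe{
#'   \item{`"weak"`}{two exposures, every SNP affects both, independent
#'     uniform effects with positive support; calibrated so the mean
#'     univariable first-stage F is ~8.8 while the mean conditional F_TS is
#'     ~3.35 (individually and conditionally weak).}
#'   \item{`"conditionally_weak"`}{two exposures whose SNP effects share a
#'     strong uniform component plus small independent components, in the
#'     spirit of local-to-zero weak-instrument asymptotics: marginally very
#'     strong (mean F in the thousands at the reference sample size) but
#'     conditionally weak (mean F_TS ~9.1).}
#'   \item{`"three_exposure"`}{three exposures; effects on exposures 1 and 3
#'     share a component (conditional F_TS ~6.6 and ~3.2) while exposure 2
#'     is independent and stays moderately strong (conditional F_TS ~17.9
#'     despite a marginal F of ~235).}
#' }
#' Marginal-strength anchors are imposed at the reference sample size
#' `n_ref = 20000`; conditional anchors at the actual `n`, so reduced-scale
#' runs preserve the conditional-weakness regime each scenario is about.
#'
#' @param scenario one of `"weak"`, `"conditionally_weak"`,
#'   `"three_exposure"`, or `"custom"` (supply all DGP fields via `...`).
#' @param n sample size of each of the two samples (default 5000; the
#'   reference studies use 20000).
#' @param L number of SNPs (default 200).
#' @param tau2 balanced-pleiotropy variance of the per-SNP direct effects on
#'   the outcome (0 = no pleiotropy).
#' @param beta true direct effects; defaults `(0.5, -0.3)` for two-exposure
#'   scenarios and `(0.5, -0.3, 0.7)` for the three-exposure one.
#' @param n_reps default number of replicates for [run_study()].
#' @param one_sample if `TRUE`, outcome associations are computed in the
#'   exposure sample (sample overlap; for diagnostics only).
#' @param ... for `scenario = "custom"`: `confounder` (length-K loading),
#'   `theta_max`, `loading`, `u_lo`, `u_hi`, and optionally `noise_x`,
#'   `noise_y`, `outcome_confounder`, `maf_range`.
#' @return an object of class `mvmr_sim_design`.
#' @export
mvmr_sim_design <- function(scenario = c("weak", "conditionally_weak",
                                         "three_exposure", "custom"),
                            n = 5000, L = 200, tau2 = 0, beta = NULL,
                            n_reps = 200, one_sample = FALSE, ...) {
  scenario <- match.arg(scenario)
  extra <- list(...)
  pars <- switch(scenario,
                 weak = .calibrate_weak(n, L),
                 conditionally_weak = .calibrate_condweak(n, L),
                 three_exposure = .calibrate_three(n, L),
                 custom = {
                   req <- c("confounder", "theta_max", "loading", "u_lo", "u_hi")
                   if (!all(req %in% names(extra))) {
                     stop("custom scenario requires: ", paste(req, collapse = ", "))
                   }
                   extra[req]
                 })
  K <- length(pars$loading)
  if (is.null(beta)) {
    beta <- if (K == 3) c(0.5, -0.3, 0.7) else c(0.5, -0.3)[seq_len(K)]
  }
  stopifnot(length(beta) == K, tau2 >= 0, L > K)
  d <- list(scenario = scenario, n = as.integer(n), L = as.integer(L), K = K,
            beta = beta, tau2 = tau2,
            confounder = pars$confounder, theta_max = pars$theta_max,
            loading = pars$loading, u_lo = pars$u_lo, u_hi = pars$u_hi,
            noise_x = if (!is.null(extra$noise_x)) extra$noise_x else 1,
            noise_y = if (!is.null(extra$noise_y)) extra$noise_y else 1,
            outcome_confounder = if (!is.null(extra$outcome_confounder))
              extra$outcome_confounder else 1,
            maf_range = if (!is.null(extra$maf_range)) extra$maf_range
            else c(0.1, 0.9),
            n_reps = as.integer(n_reps), one_sample = isTRUE(one_sample))
  class(d) <- "mvmr_sim_design"
  d
}

#' @export
print.mvmr_sim_design <- function(x, ...) {
  cat(sprintf("<mvmr_sim_design> %s: n = %d x2 samples, L = %d, K = %d, tau2 = %g\n",
              x$scenario, x$n, x$L, x$K, x$tau2))
  cat("  beta =", paste(format(x$beta), collapse = ", "),
      " confounder loading =", format(x$confounder[1], digits = 4), "\n")
  cat("  effect ranges: theta_max =", format(x$theta_max, digits = 4),
      " loadings =", paste(format(x$loading, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Draw a per-SNP effect matrix for a design
#'
#' @param design an [mvmr_sim_design()].
#' @return L x K matrix of true SNP-exposure effects pi_kj.
#' @export
draw_effects <- function(design) {
  theta <- stats::runif(design$L, 0, max(design$theta_max, 0))
  if (design$theta_max == 0) theta <- numeric(design$L)
  sapply(seq_len(design$K), function(k) {
    design$loading[k] * theta +
      stats::runif(design$L, design$u_lo[k], design$u_hi[k])
  })
}

# Per-SNP univariable regressions (with intercept) of y on every genotype
# column at once.  Residual variance divided by n by default (the package's
# stated convention) or by n - 2.
.gwas_univar <- function(G, y, df_adjust = "n") {
  n <- nrow(G)
  Gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sgg <- colSums(Gc^2)
  b <- colSums(Gc * yc) / sgg
  rss <- sum(yc^2) - b^2 * sgg
  denom <- if (df_adjust == "n") n else n - 2L
  se <- sqrt(pmax(rss, 0) / denom / sgg)
  list(beta = b, se = se)
}

.draw_sample <- function(design, Pi, alpha, f) {
  n <- design$n; L <- design$L; K <- design$K
  G <- matrix(stats::rbinom(n * L, 2L, rep(f, each = n)), n, L)
  U <- stats::rnorm(n)
  X <- G %*% Pi + tcrossprod(U, design$confounder) +
    matrix(stats::rnorm(n * K, sd = design$noise_x), n, K)
  Y <- drop(X %*% design$beta) + drop(G %*% alpha) +
    design$outcome_confounder * U + stats::rnorm(n, sd = design$noise_y)
  list(G = G, X = X, Y = Y)
}

#' Simulate one two-sample replicate
#'
#' Draws allele frequencies, true effects, pleiotropic effects and two
#' independent samples, computes per-SNP univariable summary statistics in
#' the appropriate sample (exposures in sample 1, outcome in sample 2), and
#' assembles an [mvmr_dataset()] with covariances from the requested route.
#'
#' @param design an [mvmr_sim_design()].
#' @param cov_route `"phenocorr"` (per-SNP covariances from the exposure
#'   sample's phenotypic correlation; the default), `"zero"`, or
#'   `"individual"` (exact per-SNP covariances from the exposure sample).
#' @param df_adjust residual-variance convention for the summary regressions.
#' @return list with `dataset`, the individual-level `exposure_sample` and
#'   `outcome_sample` (each `G`, `X`, `Y`), the true `Pi`, `alpha`, `f`, and
#'   the estimated phenotypic correlation `rho`.
#' @export
simulate_replicate <- function(design,
                               cov_route = c("phenocorr", "zero", "individual"),
                               df_adjust = "n") {
  cov_route <- match.arg(cov_route)
  f <- stats::runif(design$L, design$maf_range[1], design$maf_range[2])
  Pi <- draw_effects(design)
  alpha <- if (design$tau2 > 0) {
    stats::rnorm(design$L, 0, sqrt(design$tau2))
  } else numeric(design$L)

  s1 <- .draw_sample(design, Pi, alpha, f)
  s2 <- if (design$one_sample) s1 else .draw_sample(design, Pi, alpha, f)

  K <- design$K
  eb <- es <- matrix(NA_real_, design$L, K)
  for (k in seq_len(K)) {
    g <- .gwas_univar(s1$G, s1$X[, k], df_adjust)
    eb[, k] <- g$beta; es[, k] <- g$se
  }
  og <- .gwas_univar(s2$G, s2$Y, df_adjust)
  rho <- stats::cor(s1$X)

  cov_list <- switch(cov_route,
                     phenocorr = snpcov_phenocorr(rho, es),
                     zero = snpcov_zero(es),
                     individual = snpcov_individual(s1$G, s1$X, df_adjust))
  colnames(eb) <- colnames(es) <- paste0("X", seq_len(K))
  ds <- mvmr_dataset(eb, es, og$beta, og$se, cov_list)
  list(dataset = ds, exposure_sample = s1, outcome_sample = s2,
       Pi = Pi, alpha = alpha, f = f, rho = rho)
}

#' Individual-level reference estimators for a simulated replicate
#'
#' Computes, in the exposure sample (where both exposures and outcome are
#' observed), the one-sample benchmarks against which the summary-data
#' statistics are judged: multivariable OLS of Y on X, two-stage least
#' squares with all L SNPs, the per-exposure univariable (all-SNP joint
#' first-stage) F-statistic, and the conditional F-statistic F_SW computed
#' by the two-stage conditional procedure (2SLS of each exposure on the
#' others, residual regressed on the instruments, degrees of freedom
#' L - (K - 1)).
#'
#' @param rep a replicate from [simulate_replicate()].
#' @return list with `ols`, `tsls` (length-K vectors), `f`, `f_sw`
#'   (per-exposure).
#' @export
individual_references <- function(rep) {
  G <- rep$exposure_sample$G
  X <- rep$exposure_sample$X
  Y <- rep$exposure_sample$Y
  n <- nrow(G); L <- ncol(G); K <- ncol(X)

  ols <- stats::lm.fit(cbind(1, X), Y)$coefficients[-1]

  Z <- cbind(1, G)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient instrument matrix")
  Xhat <- qr.fitted(qz, X)
  tsls <- stats::lm.fit(cbind(1, Xhat), Y)$coefficients[-1]

  Xres <- qr.resid(qz, X)                       # first-stage residuals
  tss <- colSums(sweep(X, 2, colMeans(X))^2)
  rss <- colSums(Xres^2)
  f <- ((tss - rss) / L) / (rss / (n - L - 1))

  f_sw <- vapply(seq_len(K), function(k) {
    co <- stats::lm.fit(cbind(1, Xhat[, -k, drop = FALSE]),
                        X[, k])$coefficients
    e <- X[, k] - drop(cbind(1, X[, -k, drop = FALSE]) %*% co)
    er <- qr.resid(qz, e)
    tss_e <- sum((e - mean(e))^2)
    rss_e <- sum(er^2)
    ((tss_e - rss_e) / (L - (K - 1))) / (rss_e / (n - L - 1))
  }, 0)

  names(ols) <- names(tsls) <- names(f) <- names(f_sw) <- colnames(X)
  list(ols = ols, tsls = tsls, f = f, f_sw = f_sw)
}

#' Run a Monte-Carlo study over replicates of a design
#'
#' Repeats [simulate_replicate()] `n_reps` times and records, per replicate,
#' whichever statistics are requested: causal estimates (IVW / beta_Q /
#' beta_Q,het), conditional strength (F_TS per exposure), heterogeneity
#' statistics with their 5% chi-squared rejections, zero-covariance-route
#' strength, and the individual-level references.  Failed replicates are
#' counted and reported, never silently dropped.
#'
#' @param design an [mvmr_sim_design()].
#' @param what character subset of `c("ivw", "q", "qhet", "strength",
#'   "heterogeneity", "individual", "strength_zero")`.
#' @param n_reps number of replicates (default `design$n_reps`).
#' @param seed integer seed; a single seed governs the whole study.
#' @param cov_route covariance route for the summary datasets.
#' @return object of class `mvmr_study`: list with `per_rep` (data.frame,
#'   one row per replicate), `summary` (means, SDs, rejection rates),
#'   `n_failed`, `seed`, `design`.
#' @export
run_study <- function(design,
                      what = c("ivw", "q", "qhet", "strength", "heterogeneity"),
                      n_reps = design$n_reps, seed = 1L,
                      cov_route = "phenocorr") {
  what <- match.arg(what, c("ivw", "q", "qhet", "strength", "heterogeneity",
                            "individual", "strength_zero"),
                    several.ok = TRUE)
  set.seed(seed)
  crit <- stats::qchisq(0.95, df = design$L - design$K)
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rows[[r]] <- tryCatch({
      rep <- simulate_replicate(design, cov_route = cov_route)
      ds <- rep$dataset
      out <- list(rep = r)
      if ("ivw" %in% what) {
        b <- mvmr_ivw(ds)$beta
        out[paste0("ivw_", seq_along(b))] <- as.list(b)
      }
      if ("q" %in% what || "heterogeneity" %in% what) {
        qr_ <- suppressWarnings(mvmr_q(ds))
        if ("q" %in% what) {
          out[paste0("q_", seq_len(design$K))] <- as.list(qr_$estimate$beta)
        }
        if ("heterogeneity" %in% what) {
          out$qa_min <- qr_$heterogeneity$value
          out$qa_reject <- as.integer(qr_$heterogeneity$value > crit)
          qi <- q_ivw(ds); qu <- q_ivw_updated(ds)
          out$q_ivw <- qi$value
          out$q_ivw_reject <- as.integer(qi$value > crit)
          out$q_ivw_up <- qu$value
          out$q_ivw_up_reject <- as.integer(qu$value > crit)
        }
      }
      if ("qhet" %in% what) {
        qh <- suppressWarnings(mvmr_qhet(ds))
        out[paste0("qhet_", seq_len(design$K))] <- as.list(qh$beta)
        out$tau2_hat <- qh$tau2
      }
      if ("strength" %in% what) {
        st <- mvmr_strength(ds)
        out[paste0("fts_", seq_len(design$K))] <- as.list(st$f_ts)
      }
      if ("strength_zero" %in% what) {
        ds0 <- mvmr_dataset(ds$exposure_beta, ds$exposure_se,
                            ds$outcome_beta, ds$outcome_se,
                            snpcov_zero(ds$exposure_se))
        st0 <- mvmr_strength(ds0)
        out[paste0("fts0_", seq_len(design$K))] <- as.list(st0$f_ts)
      }
      if ("individual" %in% what) {
        ir <- individual_references(rep)
        out[paste0("f_", seq_len(design$K))] <- as.list(ir$f)
        out[paste0("fsw_", seq_len(design$K))] <- as.list(ir$f_sw)
        out[paste0("ols_", seq_len(design$K))] <- as.list(ir$ols)
        out[paste0("tsls_", seq_len(design$K))] <- as.list(ir$tsls)
      }
      as.data.frame(out)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      warning("replicate ", r, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(rows, is.null, TRUE)
  if (!any(ok)) {
    stop("all ", n_reps, " replicates failed; see warnings", call. = FALSE)
  }
  per_rep <- do.call(rbind, rows[ok])
  num <- per_rep[, setdiff(names(per_rep), "rep"), drop = FALSE]
  summary <- data.frame(
    statistic = names(num),
    mean = vapply(num, mean, 0),
    sd = vapply(num, stats::sd, 0),
    row.names = NULL)
  structure(list(per_rep = per_rep, summary = summary, n_failed = n_failed,
                 n_reps = n_reps, seed = seed, design = design),
            class = "mvmr_study")
}

#' @export
print.mvmr_study <- function(x, ...) {
  cat(sprintf("<mvmr_study> %s design, %d replicates (%d failed), seed %d\n",
              x$design$scenario, x$n_reps, x$n_failed, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}
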