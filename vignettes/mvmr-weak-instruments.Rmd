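---
title: "Weak instruments and pleiotropy in two-sample multivariable MR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak instruments and pleiotropy in two-sample multivariable MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmrq)
```

## The model

Multivariable Mendelian randomization (MVMR) uses $L$ genetic variants as
instruments for $K$ exposures $X_1,\dots,X_K$ to estimate the vector
$\beta$ of *direct* causal effects on an outcome $Y$.  In the two-sample
summary-data setting we observe, per SNP $j$: estimated exposure
associations $\hat\pi_j \in \mathbb R^K$ with standard errors, an outcome
association $\hat\Gamma_j$ with standard error $\sigma_{y,j}$, and (ideally)
the $K\times K$ covariance matrix $\Sigma_{V,j}$ of the estimation errors of
$\hat\pi_j$.  Under valid instruments, $\Gamma_j = \beta'\pi_j$.

Three threats structure the package:

1. **Conditional weakness.**  MVMR requires the instruments to predict each
   exposure *conditional on the others*.  Per-exposure F-statistics cannot
   detect a failure of this condition: exposures whose SNP effects are
   highly correlated can each have enormous marginal F yet be almost
   unidentified jointly.
2. **Weak-instrument bias of IVW.**  The standard estimator regresses
   $\hat\Gamma$ on $\hat\pi$ with weights $1/\sigma^2_{y,j}$, ignoring the
   error in $\hat\pi$; with weak instruments it is attenuated and mixed
   across exposures.
3. **Pleiotropy.**  Direct SNP-outcome effects inflate heterogeneity;
   standard heterogeneity tests over-reject under weak instruments, and
   balanced pleiotropy biases IVW further.

## Statistics

**Conditional strength.**  For exposure $k$, the conditional fit regresses
$\hat\pi_k$ on the other exposures' associations by inverse-variance
weighted least squares without intercept, giving $\tilde\delta$, and

$$Q_{x_k} = \sum_j \frac{(\hat\pi_{kj} - \tilde\delta'\hat\Pi_{-k,j})^2}
  {\tilde\delta^{*\prime}\,\Sigma_{V,j}\,\tilde\delta^*},
\qquad \tilde\delta^* = (\dots,-1,\dots)\ \text{with}\ {-1}\ \text{at}\ k .$$

Because the weights depend on $\tilde\delta$, the weighted fit is iterated
to a fixed point (tolerance $10^{-8}$ on the coefficients, at most 100
passes), initialized at the unweighted solution.  The fixed point solves the
weighted normal equations at converged weights; it is *not* the LIML-style
minimizer of $Q_{x_k}$ over $\delta$ (whose gradient carries an extra
weight-derivative term).  The two coincide exactly when the conditional fit
is noise-free and agree to within a few percent of $Q_{x_k}$ under strong
instruments; the regression form is used because it is the estimator the
conditional test is defined with, and direct minimization of $Q_{x_k}$ is a
different (LIML-flavoured) estimator deliberately not adopted here.  The
test statistic is $F_{TS,k} = Q_{x_k}/(L-(K-1))$, compared against tabulated
critical values (`cf_critical_value()`) for tolerated relative bias 5%, 10%
or 20%, linearly interpolated in $L$ over the grid
$\{25, 50, 100, 200, 300, 400, 500\}$ and clamped above 500; below 25
instruments the table (and the $F>10$ rule of thumb) has no support and the
lookup refuses.  $Q_{x_k}$ also yields an underidentification p-value from
$\chi^2_{L-1}$; both degrees-of-freedom conventions are reported and
labelled.

**Heterogeneity.**  With weights that include the exposure-error
contribution,

$$Q_A(\beta, \tau^2) = \sum_j
  \frac{(\hat\Gamma_j - \beta'\hat\pi_j)^2}
       {\sigma^2_{y,j} + \beta'\Sigma_{V,j}\beta + \tau^2},$$

$\min_\beta Q_A(\beta, 0)$ is an exact $\chi^2_{L-K}$ test for pleiotropy
even under weak instruments.  `q_ivw()` (weights $1/\sigma^2_{y,j}$ at the
IVW estimate) over-rejects under weak instruments; `q_ivw_updated()`
(weights and estimate iterated to a fixed point) reduces but does not
remove the over-rejection; both are provided for comparison and reported by
`mvmr_pleiotropy()` together with per-SNP contributions for outlier
screening.

**Estimation.**  `mvmr_q()` minimizes $Q_A(\beta, 0)$; `mvmr_qhet()` solves
the simultaneous system in $(\beta, \tau^2)$: $\beta$ minimizes
$Q_A(\cdot,\tau^2)$ and $Q_A(\beta,\tau^2) = L-K$, so the pleiotropy
variance $\tau^2$ absorbs excess heterogeneity.  Standard errors come from
the delete-one-SNP jackknife
$SE_k = \sqrt{\tfrac{L-1}{L}\sum_i(\hat\beta_{k,(-i)}-\bar\beta_k)^2}$,
preferred over a bootstrap because resampling SNPs can produce very weak
instrument subsets.

## Numerical choices

* $Q_A$ minimization is non-convex (the weights depend on $\beta$), so the
  optimizer is a Nelder-Mead simplex refined by BFGS with the analytic
  gradient, multistarted deterministically from the IVW estimate, zero, and
  the IVW estimate scaled by 0.5 and 1.5; a grid-search oracle in the test
  suite confirms no nearby lattice point beats the optimizer.  Under severe
  conditional weakness the objective flattens and the minimizing $\beta$
  can run to extreme values while the *minimum itself* stays well-behaved;
  estimates more than 100 times the IVW scale trigger an instability
  warning, not an error.
* The $\tau^2$ solver exploits that $Q_A$ is strictly decreasing in
  $\tau^2$ for fixed $\beta$ (so the profile is too, by the envelope
  theorem, with derivative $-\sum_j r_j^2/w_j^2$): the bracket grows
  geometrically from the IVW residual variance, then a Newton iteration
  safeguarded by bisection drives $|Q_{A,\min}(\tau^2) - (L-K)|$ below
  $10^{-8}$.  If $Q_{A,\min}(0) \le L-K$ the solution truncates to
  $\hat\tau^2 = 0$, $\hat\beta = \hat\beta_Q$.
* Per-SNP covariance matrices failing positive semi-definiteness by
  numerical noise (most negative eigenvalue within $10^{-6}$ of the largest
  in magnitude) are repaired by eigenvalue clipping; anything larger is
  rejected as invalid input, since a covariance built from a valid
  correlation matrix is PSD by construction.
* The summary-regression variance convention divides the residual sum of
  squares by $n$; a switch (`df_adjust = "n-2"`) matches software that uses
  the unbiased convention.  The phenotypic correlation used by
  `snpcov_phenocorr()` is the raw Pearson correlation of the exposures;
  residualizing first changes nothing material when each SNP explains a
  small fraction of variance, which is the regime where the approximation
  $\sigma_{km,j} = \rho_{km}\sigma_{k,j}\sigma_{m,j}$ is valid.
* SNPs with any missing or non-finite summary field are dropped (with a
  logged count) rather than imputed; dropping is conservative and keeps the
  estimand unchanged.

## The simulation designs

All designs share one data-generating process per replicate: allele
frequencies $f_j \sim U(0.1, 0.9)$; dosages $G_{ij} \sim
\mathrm{Binomial}(2, f_j)$ (a conventional choice -- any genotype law with
nondegenerate variance leaves every claim tested unchanged); exposures
$X_k = \sum_j \pi_{kj} G_j + c_k U + \epsilon_k$ with a shared standard
normal confounder $U$ and standard normal noise; outcome
$Y = \beta'X + \sum_j \alpha_j G_j + U + \epsilon_y$ with balanced
pleiotropy $\alpha_j \sim N(0, \tau^2)$.  Two independent samples of equal
size share the true $\Pi$ and $\alpha$; exposure associations are estimated
in one, outcome associations in the other, each by univariable per-SNP
regressions; per-SNP covariances use the phenotypic-correlation route with
the correlation estimated from the exposure sample.

Per-SNP effects are uniform draws, optionally loaded on a shared uniform
component $\theta_j$ to correlate exposures:
$\pi_{kj} = \lambda_k\theta_j + u_{kj}$.  Two features matter:

* **Positive-support uniforms.**  Effects drawn from $U(0, a)$ (rather than
  centred uniforms) give the effect *vectors* of different exposures a
  cosine similarity of $0.75$ even when drawn independently, because of the
  common mean direction.  This is what makes a design with "independent"
  effects simultaneously marginally adequate and conditionally weak, which
  the reference studies exhibit.
* **Anchored calibration.**  Effect ranges and confounder loadings are not
  free dials.  A closed-form second-moment model of the DGP (exact uniform
  and genotype moments; estimation-noise moments $\Sigma_X/n$ entering the
  conditional-fit probability limit) maps design constants to the expected
  marginal F, conditional $F_{TS}$, and IVW probability limit.  At design
  construction these equations are solved so each scenario hits the
  instrument-strength conditions that define it: the weak two-exposure
  scenario (mean univariable F $\approx 8.8$, mean $F_{TS} \approx 3.35$,
  IVW attenuation to $\approx(0.35, -0.13)$ from truth $(0.5, -0.3)$); the
  conditionally weak scenario (marginal F $\approx 1600$ and $3100$,
  $F_{TS} \approx 9.13$); and the three-exposure scenario (marginal F
  $\approx 236/235/14.5$, conditional $F_{TS} \approx 6.6/17.9/3.2$, with
  exposures 1 and 3 sharing effects and exposure 2 independent).  For the
  three-exposure scenario those anchors are overdetermined in this effect
  family; the solver uses a least-squares compromise in which the
  conditional strength of the two-exposure subfit enters with a small
  weight to pin down the shared-versus-independent decomposition, and the
  realized compromise sits within roughly 5-15% of each anchor.

Anchors are imposed at the actual sample size, which makes each scenario
scale-free: a run with $n = 5000$ preserves the conditional-weakness regime
of the reference $n = 20000$ studies.  One consequence is worth stating:
the individual-level conditional statistic $F_{SW}$ and the summary
statistic $F_{TS}$ differ by a wedge that grows with the ratio of the
conditional noncentrality to $n$, because the summary weights use the
*total* phenotypic residual variance while the individual-level regression
conditions on all SNPs.  At $F_{TS}\approx 9$ the wedge is $\sim 7$% at
$n = 20000$ (matching the reference studies) but $\sim 40$% at $n = 5000$;
the equivalence claim is therefore checked at the reference sample size for
the conditionally weak design and at reduced scale for the weak design,
where the wedge is small.  Per-replicate correlation between the two
statistics exceeds 0.9 everywhere.

Default study sizes (200 replicates of $n = 5000$, $L = 200$; 400-800
replicates in the acceptance script) keep a full validation run in minutes
on one CPU while leaving Monte-Carlo error well inside the comparison
tolerances; the structural conclusions are unchanged at the reference
scale.

With unit noise the pleiotropy variance $\tau^2 = 0.5$ is large relative to
$\sigma^2_{y,j}$, so the $\tau^2 = 0.5$ scenario is a *strong* pleiotropy
regime: $Q_A$ power is saturated (100% rejection) and $\hat\beta_{Q,het}$
has a visibly larger dispersion than IVW, while remaining centred on the
truth.  The reference studies' printed $Q_A$ level under pleiotropy implies
a much larger outcome noise scale; none of the claims validated here depend
on that scale.

## What the simulations do and do not show

The generator emulates: uniform per-SNP effects calibrated to target
instrument strength, Staiger-Stock-style correlated effects producing
conditionally weak instruments, balanced pleiotropy, a shared confounder,
and the two-sample split.  It does not emulate LD between variants, sample
overlap, binary outcomes, allele-coding errors, directional pleiotropy, or
winner's-curse selection of instruments -- so passing tests demonstrate the
statistics behave as claimed under the stated model, not robustness to
those features.  Allele harmonization and clumping are assumed done
upstream of the package.

## A small worked example

```{r example, eval = FALSE}
design <- mvmr_sim_design("weak", n = 5000, L = 200, tau2 = 0.5)
rep <- simulate_replicate(design)   # two-sample summary data + truth
ds <- rep$dataset

mvmr_strength(ds)                   # F_TS per exposure vs critical values
mvmr_pleiotropy(ds)                 # Q_IVW, Q_IVW,up, minimized Q_A
mvmr_ivw(ds)                        # biased under these conditions
mvmr_qhet(ds, se = "jackknife")     # robust to both threats
```

## Known limitations

* $\hat\beta_Q$ is reported but unstable under severe conditional weakness
  (flagged); $\hat\beta_{Q,het}$ handles balanced pleiotropy only --
  directional pleiotropy biases it.
* The phenotypic-correlation route inherits any error in $\rho$; use
  `rho_sensitivity()` to scan $F_{TS}$ and $\hat\beta_{Q,het}$ across
  plausible values when $\rho$ comes from a non-matching sample.
* The jackknife needs a moderate number of SNPs (the 100-200 typical of
  MVMR applications); with very few SNPs neither it nor a bootstrap is
  reliable.
* Critical values below 25 instruments are unavailable by design.
* Under the no-pleiotropy null, $\hat\tau^2 > 0$ in about half of
  replicates (as expected for an exact test at its dof); the resulting
  reweighting can shrink the estimate for a conditionally weak exposure by
  a small amount relative to $\hat\beta_Q$ at reduced sample sizes.
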