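# Monte-Carlo studies shared by several acceptance-criterion tests.  Each is
# computed once per test run (lazily) and cached; reduced scale is 200
# replicates with two samples of n = 5000, L = 200 SNPs.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(name, builder) {
  if (!exists(name, envir = .study_cache)) {
    assign(name, builder(), envir = .study_cache)
  }
  get(name, envir = .study_cache)
}

weak_null_study <- function() cached_study("weak_null", function() {
  d <- mvmr_sim_design("weak", n = 5000, L = 200, tau2 = 0)
  run_study(d, what = "heterogeneity", n_reps = 200, seed = 104729)
})

weak_pleio_study <- function() cached_study("weak_pleio", function() {
  d <- mvmr_sim_design("weak", n = 5000, L = 200, tau2 = 0.5)
  suppressWarnings(
    run_study(d, what = c("ivw", "qhet", "strength", "heterogeneity"),
              n_reps = 200, seed = 104729))
})

condweak_null_study <- function() cached_study("condweak_null", function() {
  d <- mvmr_sim_design("conditionally_weak", n = 5000, L = 200, tau2 = 0)
  run_study(d, what = "heterogeneity", n_reps = 200, seed = 104729)
})

condweak_strength_study <- function() cached_study("condweak_strength", function() {
  d <- mvmr_sim_design("conditionally_weak", n = 5000, L = 200)
  run_study(d, what = c("strength", "strength_zero"), n_reps = 25,
            seed = 104729)
})

three_exposure_study <- function() cached_study("three_exposure", function() {
  d <- mvmr_sim_design("three_exposure", n = 5000, L = 200)
  suppressWarnings(
    run_study(d, what = c("ivw", "qhet", "strength"), n_reps = 200,
              seed = 104729))
})

# F_TS vs F_SW equivalence runs: the weak pair at the reduced sample size,
# and the conditionally-weak pair at the reference sample size n = 20000
# (the summary-vs-individual wedge scales with noncentrality / n, so the
# printed pair is a statement about the reference scale).
weak_equiv_study <- function() cached_study("weak_equiv", function() {
  d <- mvmr_sim_design("weak", n = 5000, L = 200)
  run_study(d, what = c("strength", "individual"), n_reps = 60, seed = 104729)
})

condweak_equiv_study <- function() cached_study("condweak_equiv", function() {
  d <- mvmr_sim_design("conditionally_weak", n = 20000, L = 200)
  run_study(d, what = c("strength", "individual"), n_reps = 12, seed = 104729)
})
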