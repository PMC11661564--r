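# Shared replicated-study fixtures for the benchmark tests: each scenario is
# simulated once per test run and reused by every block that needs it.
.study_cache <- new.env(parent = emptyenv())

benchmark_study <- function(scenario) {
  key <- paste0("s", scenario)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  spec <- switch(as.character(scenario),
    "1" = list(families = "poisson",
               plan = data.frame(estimator = c("crude", "gcomp", "ltmle"),
                                 family = "poisson")),
    "2" = list(families = c("poisson", "logbin"),
               plan = data.frame(estimator = c("iptw", "iptw", "ltmle"),
                                 family = c("logbin", "poisson", "poisson"))),
    "3" = list(families = "poisson",
               plan = data.frame(estimator = c("crude", "iptw"),
                                 family = "poisson")))
  cfg <- study_config(scenario = scenario, R = 200, n = 5000, J = 3, s = 3,
                      seed = 73, families = spec$families, B = 0,
                      plan = spec$plan,
                      truth_mc_reps = 20, truth_mc_n = 25000,
                      n_truth_obs = 50000)
  res <- suppressWarnings(run_study(cfg))
  .study_cache[[key]] <- res
  res
}

study_cell <- function(res, est, fam, term) {
  s <- res$summary
  s[s$estimator == est & s$family == fam & s$term == term, ]
}
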