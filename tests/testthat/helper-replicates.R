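# Shared replicate studies for the operating-characteristic tests. Studies
# are simulated and fitted once per test run and reused across test blocks;
# priors compared on the same setting share the same simulated datasets.

.acc <- new.env(parent = emptyenv())

acc_reps <- 50L
acc_iters <- 3000L
acc_burnin <- 500L

acc_datasets <- function(scenario, sigma_u2, sigma_eps2, seed_base,
                         n = 500L) {
  key <- paste("data", scenario, sigma_u2, sigma_eps2, seed_base, sep = "_")
  if (is.null(.acc[[key]])) {
    design <- simulation_design(n = n, scenario = scenario,
                                sigma_u2 = sigma_u2, sigma_xi2 = 0.25,
                                sigma_eps2 = sigma_eps2)
    .acc[[key]] <- lapply(seq_len(acc_reps), function(r)
      simulate_joint(design, seed = seed_base + r))
  }
  .acc[[key]]
}

acc_study <- function(variant, scenario, sigma_u2, sigma_eps2, seed_base) {
  key <- paste("study", variant, scenario, sigma_u2, sigma_eps2, seed_base,
               sep = "_")
  if (is.null(.acc[[key]])) {
    design <- simulation_design(n = 500L, scenario = scenario,
                                sigma_u2 = sigma_u2, sigma_xi2 = 0.25,
                                sigma_eps2 = sigma_eps2)
    datasets <- acc_datasets(scenario, sigma_u2, sigma_eps2, seed_base)
    .acc[[key]] <- replicate_study(design, prior_config(variant),
                                   reps = acc_reps, iters = acc_iters,
                                   burnin = acc_burnin, seed = seed_base,
                                   datasets = datasets)
  }
  .acc[[key]]
}

# per-replicate false-negative counts for one submodel
acc_fn_counts <- function(study, submodel = c("longitudinal", "survival")) {
  submodel <- match.arg(submodel)
  pos <- if (submodel == "longitudinal") study$report$positives_theta
         else study$report$positives_beta
  tr <- if (submodel == "longitudinal") study$truth$theta else study$truth$beta
  colSums(!pos & tr != 0)
}
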