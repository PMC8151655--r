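library(dplyr)

# noise-free multi-dose series builders used across test files
uncomp_series <- function(Ki = 0.009, doses = c(0.005, 0.01, 0.02),
                          noise_cv = 0, seed = NULL) {
  simulate_kinetic_series(
    kinetic_truth(0.007, 1111, "uncompetitive", Ki = Ki, noise_cv = noise_cv),
    doses = doses, seed = seed)
}

comp_series <- function(Ki = 0.05, doses = c(0.02, 0.05, 0.1),
                        noise_cv = 0, seed = NULL) {
  simulate_kinetic_series(
    kinetic_truth(0.06, 120.5, "competitive", Ki = Ki, noise_cv = noise_cv),
    doses = doses, seed = seed)
}

agent_split <- function(sim) {
  list(a1 = dplyr::filter(sim$agents, agent == 1),
       a2 = dplyr::filter(sim$agents, agent == 2))
}

full_ci <- function(truth, x = 0.5, seed = NULL, B = 0, ...) {
  sim <- simulate_mixture_series(truth, seed = seed, ...)
  ag <- agent_split(sim)
  combination_index(sim$mixtures, ag$a1, ag$a2, x = x, B = B, seed = seed)
}
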