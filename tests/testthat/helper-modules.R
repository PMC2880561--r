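# Shared builders for randomized module parameter draws. All randomness in
# tests flows through explicit set.seed() calls at the call sites.

rand_growth <- function(pools, rho = 1) {
  growth_params(mu_max = runif(1, 0.5, 2),
                sigma = stats::setNames(runif(length(pools), 0.5, 2), pools),
                rho = rho)
}

rand_module <- function(module) {
  switch(module,
    linear = module_params(
      "linear", list(J_max = runif(1, 0, 3)),
      list(input = feedback_term(runif(1, 1, 100), sample(c(1, 2, 4), 1))),
      growth = rand_growth("P")),
    bidirectional = module_params(
      "bidirectional",
      list(J1_max = runif(1, 0, 3), J2_max = runif(1, 0, 3),
           Jc_max = runif(1, 0, 2)),
      list(input1 = feedback_term(50), input2 = feedback_term(50),
           J12 = feedback_term(10), J21 = feedback_term(10)),
      list(J12 = saturation_term(10, 2L), J21 = saturation_term(10, 2L)),
      rand_growth(c("P1", "P2"))),
    cycle = module_params(
      "cycle", list(J_in_max = runif(1, 0, 3), Jc_max = runif(1, 0, 3)),
      list(input = feedback_term(100), conversion = feedback_term(100)),
      list(input = saturation_term(0.1), conversion = saturation_term(1)),
      rand_growth(c("E", "Q"), rho = c(E = 0.85, Q = 0.15))),
    integration = module_params(
      "integration",
      list(J_C_max = runif(1, 0, 3), J_N1_max = runif(1, 0, 1),
           J_N2_max = runif(1, 0, 3)),
      list(C = feedback_term(100), N1 = feedback_term(1000),
           N2 = feedback_term(50)),
      growth = rand_growth(c("C", "N")),
      carbon_cost = runif(1, 0.5, 2)))
}

rand_state <- function(params, max = 50) {
  pools <- module_pools(params)
  stats::setNames(runif(length(pools), 0, max), pools)
}
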