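# Shared fixtures: parameter draws used by the property-style tests.

wt_energies <- function() dnax_energies("wt")

random_energy_params <- function() {
  energy_params(delta_E = runif(1, 0.5, 5),
                delta_ESD2 = runif(1, 0, 1),
                delta_delta_ESD = runif(1, 0, 3),
                E_bp = runif(1, 0, 4),
                E_PE50S = runif(1, 2, 12))
}

random_sampling_rates <- function() {
  k20 <- runif(1, 0.05, 0.5)
  sampling_rates(k20 = k20,
                 k21 = k20 * runif(1, 0.3, 3),
                 k22 = k20 * runif(1, 0.5, 2),
                 k23 = k20 * runif(1, 20, 80),
                 k26 = runif(1, 0.1, 0.6),
                 k27 = runif(1, 20, 50),
                 k28 = runif(1, 15, 40))
}

random_arrival_params <- function() {
  arrival_params(kb1_G = runif(1, 0.2, 0.6),
                 kb1_TC = runif(1, 0.1, 0.3),
                 T_G = runif(1, 0.8, 1.8),
                 conc_EFG = runif(1, 0.05, 0.5),
                 conc_TC = runif(1, 0.2, 1))
}

random_lifetime_params <- function() {
  p_lp1 <- runif(1, 0.2, 0.5)
  p_e1 <- runif(1, 0.1, 0.3)
  lifetime_params(kb_G = runif(1, 1, 2),
                  kb1_G = runif(1, 0.3, 0.6),
                  kb1_TC = runif(1, 0.1, 0.3),
                  kr = runif(1, 1.5, 5),
                  conc_EFG = runif(1, 0.05, 0.5),
                  conc_TC = runif(1, 0.5, 2),
                  p_e1 = p_e1, p_lp1 = p_lp1,
                  N = runif(1, 1.5, 3),
                  T_tRNA = runif(1, 5, 40),
                  T_G = runif(1, 0.8, 1.8),
                  T_NR = runif(1, 5, 20))
}

expect_within_se <- function(est, closed, n_se = 3) {
  expect_lt(abs(est[["mean"]] - closed), n_se * est[["se"]])
}
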