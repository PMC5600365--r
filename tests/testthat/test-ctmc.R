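# The stochastic simulator: determinism, dwell-time sanity, branch
# recovery, and agreement of the trajectory estimators with the closed
# forms on the preset networks.

test_that("seeded runs are bit-reproducible", {
  net <- network_preset("fig3_wt_slippery")
  a <- simulate_network(net, 200, seed = 7)
  b <- simulate_network(net, 200, seed = 7)
  expect_identical(a$events, b$events)
  c <- simulate_network(net, 200, seed = 8)
  expect_false(identical(a$events, c$events))
})

test_that("state dwell times are exponential with the declared rates", {
  net <- build_network("single_stranded")
  sim <- simulate_network(net, 2e4, seed = 51)
  ev <- sim$events
  dur <- diff(c(0, ev$time))
  # C0 dwell: 1/k01; H0 dwell: EF-G binding wait
  for (chk in list(c("C0", 25), c("H0", 1.5625 * 0.08))) {
    d <- dur[ev$from == chk[1]]
    expect_within_se(c(mean = mean(d), se = sd(d) / sqrt(length(d))),
                     1 / as.numeric(chk[2]))
  }
})

test_that("branch outcome frequencies recover the Boltzmann probabilities", {
  en <- wt_energies()
  b <- branch_probabilities(en)
  net <- build_network("duplex_slippery", branch = b)
  sim <- simulate_network(net, 5000, seed = 52)
  out <- sim$events$to[sim$events$from == "H2"]
  n <- length(out)
  for (chk in list(c("LP", b$p_lp1), c("H2E", b$p_e1), c("FC", b$p_f1))) {
    p <- as.numeric(chk[2])
    expect_lt(abs(mean(out == chk[1]) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("rate-based branch rendering matches the probabilistic one", {
  en <- wt_energies()
  b <- branch_probabilities(en)
  net_p <- build_network("duplex_slippery", branch = b)
  net_r <- build_network("duplex_slippery", branch = b,
                         branch_mode = "rates", branch_rate = 1e5)
  s_p <- summarize_trajectories(simulate_network(net_p, 4000, seed = 53))
  s_r <- summarize_trajectories(simulate_network(net_r, 4000, seed = 54))
  se <- sqrt(s_p$p_lp_hat[["se"]]^2 + s_r$p_lp_hat[["se"]]^2)
  expect_lt(abs(s_p$p_lp_hat[["mean"]] - s_r$p_lp_hat[["mean"]]), 3 * se)
})

test_that("network construction rejects inconsistent configurations", {
  expect_error(build_network("duplex_slippery"), "branch")
  b <- branch_probabilities(wt_energies())
  expect_error(build_network("duplex_nonslippery", branch = b),
               "p_lp1")
  expect_error(build_network("duplex_slippery", branch = b,
                             conc_EFG = 0), "conc_EFG")
  # single-stranded network has no futile or long-pause states
  net1 <- build_network("single_stranded")
  expect_false(any(c("FC", "LP") %in% net1$states$name))
  net2 <- build_network("duplex_nonslippery",
                        branch = branch_probs(p_lp1 = 0, p_e1 = 0.25))
  expect_true("FC" %in% net2$states$name)
  expect_false("LP" %in% net2$states$name)
})

test_that("wild-type preset reproduces the headline observables", {
  net <- network_preset("fig3_wt_slippery")
  s <- summarize_trajectories(simulate_network(net, 2e4, seed = 55))
  expect_within_se(s$p_lp_hat, 0.75)
  expect_within_se(s$n_samplings_hat, 2)
  r <- net$params$sampling_effective
  expect_within_se(s$t_trna_hat, mean_trna_lifetime(r, "markov"))
  # rotated dwell of the unobstructed preset: ~8 s at 80 nM EF-G
  s1 <- summarize_trajectories(
    simulate_network(network_preset("fig1_single_stranded"), 2e4,
                     seed = 56))
  expect_within_se(s1$t_rot_hat, 8, n_se = 4)  # includes the 1/k4 step
})

test_that("frame bookkeeping splits paused ribosomes when a 0-frame tRNA competes", {
  b <- branch_probabilities(wt_energies())
  net <- build_network("duplex_slippery", branch = b, p_frame0 = 0.4)
  s <- summarize_trajectories(simulate_network(net, 4000, seed = 57))
  # frameshifted fraction = p_lp * (1 - p_frame0) within binomial error
  expect_lt(abs(s$frameshift_fraction[["mean"]] -
                  s$p_lp_hat[["mean"]] * 0.6),
            3 * sqrt(0.45 * 0.55 / 4000) +
              3 * s$p_lp_hat[["se"]] * 0.6)
  expect_lt(s$frameshift_fraction[["mean"]], s$p_lp_hat[["mean"]])
})

test_that("synthetic trace tables carry per-molecule clocks and round-trip", {
  tr <- generate_synthetic_traces("fig3_wt_slippery", 25, seed = 58)
  expect_setequal(unique(tr$events$molecule_id), 1:25)
  # per-molecule times start after zero and increase
  for (m in c(1, 13, 25)) {
    tm <- tr$events$time_s[tr$events$molecule_id == m]
    expect_true(all(diff(tm) >= 0))
    expect_gt(tm[1], 0)
  }
  # every molecule ends back at the initial state
  last <- tapply(seq_len(nrow(tr$events)), tr$events$molecule_id, max)
  expect_true(all(tr$events$target_state[last] == "C0"))

  p <- withr::local_tempfile(fileext = ".tsv")
  write_trace_events(tr, p)
  hdr <- readLines(p, n = 2)
  expect_match(hdr[2], "seed: 58")
  back <- read.delim(p, comment.char = "#")
  expect_equal(nrow(back), nrow(tr$events))
  expect_equal(back$time_s, tr$events$time_s, tolerance = 1e-9)

  empty <- generate_synthetic_traces("fig3_wt_slippery", 0, seed = 1)
  expect_equal(nrow(empty$events), 0L)
  expect_error(generate_synthetic_traces("nonesuch", 5, seed = 1))
})

test_that("force preset frameshift fraction follows the force-tilted branching", {
  net0 <- network_preset("force_sweep", force = force_context(F_pN = 0))
  s0 <- summarize_trajectories(simulate_network(net0, 2e4, seed = 59))
  expect_within_se(s0$frameshift_fraction, 0.029314,
                   n_se = 3)
  net10 <- network_preset("force_sweep", force = force_context(F_pN = 10))
  s10 <- summarize_trajectories(simulate_network(net10, 5000, seed = 60))
  p10 <- branch_probabilities_force(3.5, dnax_energies("wt")$E_PE50S,
                                    force_context(F_pN = 10))$p_lp
  expect_within_se(s10$frameshift_fraction, p10)
  expect_gt(s10$frameshift_fraction[["mean"]],
            s0$frameshift_fraction[["mean"]])
})
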