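# Sampling statistics of the long-paused rotated state.

test_that("dissociation probabilities are exponential-race outcomes", {
  expect_equal(p_dissoc_pre(sampling_rates(1, 1, 1, 1)), 0.5)
  expect_equal(p_dissoc_pre(sampling_rates(1, 1e-12, 1, 1)), 1e-12 / (1 + 1e-12))
  expect_equal(p_dissoc_pre(sampling_rates(1, 3, 1, 1)), 0.75)
  expect_equal(p_dissoc_post(sampling_rates(1, 1, 1, 1)), 0.5)
  expect_equal(p_dissoc_post(sampling_rates(1, 1, 1, 4)), 0.8)
  expect_gt(p_dissoc_post(sampling_rates(1, 1, 1, 50)), 0.98)

  # Monte-Carlo race of two exponential clocks as an independent check
  set.seed(21)
  n <- 2e5
  expect_equal(mean(rexp(n, 3) < rexp(n, 1)), 0.75,
               tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.75)
})

test_that("mean sampling number is the geometric retry count", {
  expect_equal(mean_samplings(sampling_rates(1, 1, 1, 1)), 2)
  expect_equal(mean_samplings(sampling_rates(2, 1, 1, 1)), 1.5)
  expect_equal(mean_samplings(sampling_rates(1, 1e-12, 1, 1)), 1,
               tolerance = 1e-11)
  # simulated Bernoulli retries with the race probability
  set.seed(22)
  p <- p_dissoc_pre(sampling_rates(2, 1, 1, 1))
  draws <- rgeom(2e5, prob = 1 - p) + 1
  expect_equal(mean(draws), 1.5, tolerance = 3 * sd(draws) / sqrt(2e5) / 1.5)
  # identity with the dissociation probability, for random rates
  set.seed(23)
  for (i in 1:20) {
    r <- random_sampling_rates()
    expect_equal(mean_samplings(r), 1 / (1 - p_dissoc_pre(r)),
                 tolerance = 1e-12)
  }
})

test_that("lifetime components equal their defining double integrals", {
  set.seed(24)
  for (i in 1:5) {
    r <- random_sampling_rates()
    comp <- trna_lifetime_components(r)
    # T1 = int f23(t) int_0^t t' g23(t') dt' dt, evaluated numerically
    inner <- function(t, k) 1 / k - exp(-k * t) * (t + 1 / k)
    t1_num <- integrate(function(t)
      r$k20 * exp(-r$k20 * t) * inner(t, r$k21), 0, Inf,
      rel.tol = 1e-12)$value
    expect_equal(comp$T1, t1_num, tolerance = 1e-9)
    t2_num <- 1 / r$k20 + integrate(function(t)
      r$k22 * exp(-r$k22 * t) * inner(t, r$k23), 0, Inf,
      rel.tol = 1e-12)$value
    expect_equal(comp$T2, t2_num, tolerance = 1e-9)
    expect_equal(comp$T3,
                 1 / r$k20 + 1 / r$k22 + 1 / r$k26 + 1 / r$k27 + 1 / r$k28)
  }
})

test_that("combined lifetime equals its expanded form on random rates", {
  set.seed(25)
  for (i in 1:20) {
    r <- random_sampling_rates()
    expect_equal(mean_trna_lifetime(r, "integral"),
                 mean_trna_lifetime(r, "expanded"), tolerance = 1e-10)
  }
})

test_that("without dissociation every lifetime method gives the pass-through time", {
  r <- sampling_rates(k20 = 0.5, k21 = 1e-9, k22 = 0.5, k23 = 1e-9,
                      k26 = 0.2, k27 = 30, k28 = 25)
  t3 <- trna_lifetime_components(r)$T3
  expect_equal(mean_trna_lifetime(r, "integral"), t3, tolerance = 1e-6)
  expect_equal(mean_trna_lifetime(r, "markov"), t3, tolerance = 1e-6)
})

test_that("calibration reproduces the observed sampling aggregates", {
  r <- calibrate_sampling_rates(T_tRNA = 30, N = 2)
  expect_equal(mean_samplings(r), 2, tolerance = 1e-9)
  expect_equal(mean_trna_lifetime(r), 30, tolerance = 1e-8)
  expect_equal(r$k21 / r$k20, 1, tolerance = 1e-9)
  expect_gt(r$k23 / r$k22, 10)  # dominant dissociation channel
})

test_that("factor-arrival competition follows the binding fluxes", {
  expect_equal(p_efg_binding(arrival_params(kb1_G = 0.2, kb1_TC = 0.1,
                                            conc_EFG = 0.1,
                                            conc_TC = 0.2)), 0.5)
  expect_equal(p_efg_binding(arrival_params(kb1_G = 0.41, kb1_TC = 0.16,
                                            conc_EFG = 0.08,
                                            conc_TC = 0.2)),
               0.0328 / (0.0328 + 0.032), tolerance = 1e-12)
  expect_equal(p_efg_binding(arrival_params(conc_EFG = 0)), 0)
})

test_that("mean arrival time is affine in [EF-G] with the flux intercept", {
  # no EF-G interference: pure inverse ternary-complex flux
  expect_equal(mean_arrival_time(arrival_params(kb1_G = 0.5 / 1.22,
                                                T_G = 1.22,
                                                kb1_TC = 0.16,
                                                conc_EFG = 0,
                                                conc_TC = 0.2)),
               31.25, tolerance = 1e-9)
  set.seed(26)
  for (i in 1:10) {
    ap <- random_arrival_params()
    tau0 <- mean_arrival_time(ap)
    ap2 <- ap; ap2$conc_EFG <- ap$conc_EFG * 2
    dtau <- mean_arrival_time(ap2) - tau0
    expect_equal(dtau,
                 ap$T_G * ap$kb1_G * ap$conc_EFG / (ap$kb1_TC * ap$conc_TC),
                 tolerance = 1e-10)
    # identity with the visit-count decomposition
    expect_equal(tau0,
                 mean_efg_visits(ap) * ap$T_G + 1 / (ap$kb1_TC * ap$conc_TC),
                 tolerance = 1e-10)
    # decreasing in [TC]
    ap3 <- ap; ap3$conc_TC <- ap$conc_TC * 2
    expect_lt(mean_arrival_time(ap3), tau0)
  }
  expect_error(mean_arrival_time(arrival_params(conc_TC = 0)),
               "infeasible|conc_TC")
})

test_that("sampling statistics are concentration-independent", {
  r <- calibrate_sampling_rates()
  # N and T_tRNA contain no concentration: changing the competition
  # parameters must leave them untouched
  n0 <- mean_samplings(r); t0 <- mean_trna_lifetime(r)
  expect_identical(mean_samplings(r), n0)
  expect_identical(mean_trna_lifetime(r), t0)
  # and the network-level estimates agree across concentrations (small
  # runs; the equality is structural, not statistical fine-tuning)
  net_lo <- network_preset("fig3_wt_slippery", conc_EFG = 0.04)
  net_hi <- network_preset("fig3_wt_slippery", conc_EFG = 0.32)
  s_lo <- summarize_trajectories(simulate_network(net_lo, 3000, seed = 27))
  s_hi <- summarize_trajectories(simulate_network(net_hi, 3000, seed = 28))
  se <- sqrt(s_lo$n_samplings_hat[["se"]]^2 + s_hi$n_samplings_hat[["se"]]^2)
  expect_lt(abs(s_lo$n_samplings_hat[["mean"]] -
                  s_hi$n_samplings_hat[["mean"]]), 3 * se)
})
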