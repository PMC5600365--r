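# The parameter-extraction chain and report generation.

test_that("the extraction chain recovers the published parameter set", {
  rep <- run_inference_chain(observed_aggregates())
  val <- function(q) rep$value[rep$quantity == q]
  expect_equal(val("p_e1_sd"), 0.25)
  expect_equal(val("p_lp1"), 0.43, tolerance = 0.005 / 0.43)
  expect_equal(val("p_e1"), 0.14, tolerance = 0.005 / 0.14)
  expect_equal(val("n2_G"), 1.75, tolerance = 1e-9)
  expect_equal(val("n_lp_G"), 4.73, tolerance = 0.01 / 4.73)
  expect_equal(val("t_G"), 1.22, tolerance = 0.01 / 1.22)
  expect_equal(val("kb1_G"), 0.41, tolerance = 0.005 / 0.41)
  expect_equal(val("kb_G"), 1.56, tolerance = 0.01 / 1.56)
  expect_equal(val("k21_over_k20"), 1)
  expect_equal(val("delta_E"), 3, tolerance = 0.05 / 3)
  expect_equal(val("delta_delta_ESD"), 1.6, tolerance = 0.05 / 1.6)
  expect_equal(val("E_bp"), 2.5, tolerance = 0.05 / 2.5)
})

test_that("a degenerate binding count collapses the chain cleanly", {
  rep <- run_inference_chain(observed_aggregates(n2_G_sd = 1))
  val <- function(q) rep$value[rep$quantity == q]
  expect_equal(val("p_e1_sd"), 1)
  expect_equal(val("p_lp1"), 0.75)  # transfer relation with p_e1_sd = 1
  expect_equal(val("n2_G"), 1)
})

test_that("extraction chain closes the loop on simulated aggregates", {
  # measure the aggregates from a simulation of the wild-type network,
  # push them through the chain, and compare with the preset parameters
  net <- network_preset("fig3_wt_slippery")
  s <- summarize_trajectories(simulate_network(net, 2e4, seed = 71))
  b <- net$branch
  ps <- b$p_e1 + b$p_lp1
  obs <- observed_aggregates(
    p_lp_wt = s$p_lp_hat[["mean"]],
    n2_G_sd = 4,
    n3_G = s$n_efg_hat[["mean"]],
    t2_G_sd = s$t_efg_canonical_hat[["mean"]],
    t3_G = s$t_efg_hat[["mean"]],
    N_samplings = s$n_samplings_hat[["mean"]])
  rep <- run_inference_chain(obs)
  val <- function(q) rep$value[rep$quantity == q]
  expect_equal(val("n2_G"), 1 / ps, tolerance = 0.02)
  expect_equal(val("t_G"), 1.22, tolerance = 0.03)
  expect_equal(val("n_lp_G"),
               mean_samplings(net$params$sampling_effective) *
                 mean_efg_visits(arrival_params(kb1_G = 0.41, T_G = 1.22,
                                                conc_EFG = 0.08,
                                                conc_TC = 0.2)),
               tolerance = 0.05)
})

test_that("frame-budget arithmetic matches the reported window", {
  expect_equal(uncoupled_frame_budget(0.71, 0.49), 0.22)
  expect_equal(uncoupled_frame_budget(0.75, 0.49), 0.26)
  expect_equal(uncoupled_frame_budget(0.4, 0.4), 0)
  expect_error(uncoupled_frame_budget(0.4, 0.5), ">=")
  expect_equal(multi_pulse_probability(0.71, 0.5), 0.355)
  expect_equal(multi_pulse_probability(0, 0.9), 0)
  expect_equal(multi_pulse_probability(1, 1), 1)
})

test_that("report bundle is complete, deterministic, and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- reproduce_all(d1)
  r2 <- reproduce_all(d2)
  expected <- c("p_lp_table", "tau_vs_efg", "tau_vs_tc", "tr3_vs_efg",
                "tr3_vs_tc", "tr3_mutants", "pfs_vs_force",
                "inference_chain", "regression_table")
  for (nm in expected)
    expect_true(file.exists(r1$paths[[nm]]))
  # pure function of the configuration: identical bundles
  for (nm in expected)
    expect_identical(readLines(r1$paths[[nm]]), readLines(r2$paths[[nm]]))
  expect_true(r1$all_pass)
  expect_true(all(r1$tables$regression_table$pass))
  # the force grid starts at the zero-force single-site efficiency
  g <- r1$tables$pfs_vs_force
  first <- g$p_fs[g$F_pN == 0 & g$n == 1]
  expect_equal(first, 0.029, tolerance = 0.0005 / 0.029)
  # efficiency grows with force and with the number of slippery sites
  expect_true(all(tapply(g$p_fs, g$n, function(x) all(diff(x) > 0))))
  expect_true(all(tapply(g$p_fs, g$F_pN, function(x) all(diff(x) > 0))))
})

test_that("parameter configs read back from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("delta_E: 3", "delta_delta_ESD: 1.6", "E_bp: 2.5",
               "E_PE50S: 8", "F_pN: 5", "p_nm: 0.34", "n_slippery: 2",
               "kb1_G: 0.41", "kb1_TC: 0.16", "T_G: 1.22",
               "conc_EFG: 0.08", "conc_TC: 0.2",
               "k4: 35", "k6: 5", "k7: 20"), y)
  cfg <- read_params_config(y)
  expect_s3_class(cfg$energy, "energy_params")
  expect_equal(cfg$energy$delta_E, 3)
  expect_equal(cfg$force$n_slippery, 2L)
  expect_equal(cfg$arrival$kb1_G, 0.41)
  expect_equal(efg_lifetime_simple(cfg$elong), 0.28, tolerance = 0.02)

  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(k20 = 0.02, k21 = 0.02, k22 = 0.02,
                            k23 = 1.0), j, auto_unbox = TRUE)
  cfg2 <- read_params_config(j)
  expect_s3_class(cfg2$sampling, "sampling_rates")
  expect_equal(mean_samplings(cfg2$sampling), 2)
  expect_error(read_params_config(file.path(tempdir(), "none.yaml")),
               "no such file")
})
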