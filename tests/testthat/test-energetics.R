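# Boltzmann branching at the unlocked state and its inversions.

test_that("per-codon pause probability reproduces the three constructs", {
  expect_equal(p_long_pause(3, 1.6, 2.5), 0.75, tolerance = 0.005 / 0.75)
  expect_equal(p_long_pause(3, 0, 2.5), 0.38, tolerance = 0.005 / 0.38)
  expect_equal(p_long_pause(3, 1.6, 0), 0.20, tolerance = 0.005 / 0.20)
  expect_identical(p_long_pause(0, 0, 0), 0.5)
})

test_that("branch probabilities are normalized Boltzmann weights", {
  # symmetric barriers: all three channels equally likely
  sym <- energy_params(delta_E = 0, delta_ESD2 = 0, delta_ESD3 = 0,
                       E_bp = 0, E_PE50S = 0)
  b <- branch_probabilities(sym)
  expect_equal(b$p_lp1, 1 / 3, tolerance = 1e-12)
  expect_equal(b$p_e1, 1 / 3, tolerance = 1e-12)
  expect_equal(b$p_f1, 1 / 3, tolerance = 1e-12)

  # suppressing the futile channel leaves the two-way logistic split
  wt_no_fc <- energy_params(delta_E = 3, delta_ESD2 = 0,
                            delta_ESD3 = 1.6, E_bp = 2.5, E_PE50S = Inf)
  b <- branch_probabilities(wt_no_fc)
  expect_equal(b$p_f1, 0)
  expect_equal(b$p_lp, 0.75, tolerance = 0.005 / 0.75)

  # generic parameter set against a direct hand evaluation of the weights
  en <- energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6,
                      E_bp = 2.5, E_PE50S = 4)
  b <- branch_probabilities(en)
  w <- c(exp(-(3 + 0 + 2 * 2.5)), exp(-(1.6 + 3 * 2.5)), exp(-4))
  expect_equal(b$p_lp1, w[1] / sum(w), tolerance = 1e-12)
  expect_equal(b$p_e1, w[2] / sum(w), tolerance = 1e-12)
  expect_equal(b$p_f1, w[3] / sum(w), tolerance = 1e-12)
})

test_that("normalization and pause-ratio identities hold for random parameters", {
  set.seed(11)
  for (i in 1:25) {
    en <- random_energy_params()
    b <- branch_probabilities(en)
    expect_lt(abs(b$p_lp1 + b$p_e1 + b$p_f1 - 1), 1e-12)
    expect_lt(abs(b$p_lp + b$p_nor - 1), 1e-12)
    expect_lt(abs(b$p_lp - b$p_lp1 / (b$p_lp1 + b$p_e1)), 1e-12)
    # the logistic form must agree with the weight ratio
    expect_equal(b$p_lp,
                 p_long_pause(en$delta_E, en$delta_delta_ESD, en$E_bp),
                 tolerance = 1e-12)
  }
})

test_that("pause probability is monotone in each energy", {
  g <- seq(0.1, 4, by = 0.3)
  expect_true(all(diff(p_long_pause(3, 1.6, g)) > 0))
  expect_true(all(diff(p_long_pause(3, g, 2.5)) > 0))
  expect_true(all(diff(p_long_pause(g, 1.6, 2.5)) < 0))
})

test_that("force-dependent branching matches its zero-force and high-force limits", {
  # zero force, futile branch suppressed: logistic of -delta_E
  b0 <- branch_probabilities_force(3.5, Inf, force_context(F_pN = 0))
  expect_equal(b0$p_lp, exp(-3.5) / (1 + exp(-3.5)), tolerance = 1e-12)
  # agrees with the hairpin-free SD-free specialization of the
  # zero-force branching
  en <- energy_params(delta_E = 3.5, E_bp = 0, E_PE50S = 5)
  bf <- branch_probabilities_force(3.5, 5, force_context(F_pN = 0))
  bz <- branch_probabilities(en)
  expect_equal(bf$p_lp1, bz$p_lp1, tolerance = 1e-12)
  expect_equal(bf$p_e1, bz$p_e1, tolerance = 1e-12)
  # large force drives the pause probability to one
  bL <- branch_probabilities_force(3.5, Inf, force_context(F_pN = 500))
  expect_gt(bL$p_lp, 0.999)
  # generic force evaluated two ways: logistic form vs weight ratio
  ctx <- force_context(F_pN = 10, p_nm = 0.34, kBT_pN_nm = 4.1)
  b10 <- branch_probabilities_force(3.5, 6, ctx)
  fp <- 10 * 0.34 / 4.1
  expect_equal(b10$p_lp, plogis(-(3.5 - fp)), tolerance = 1e-12)
  w <- c(exp(-(3.5 + 2 * fp)), exp(-3 * fp), exp(-6))
  expect_equal(b10$p_lp1, w[1] / sum(w), tolerance = 1e-12)
  expect_error(force_context(F_pN = -1), "F_pN")
})

test_that("total frameshift probability compounds independent sites", {
  expect_equal(total_frameshift_prob(0.0293, 1), 0.0293)
  p <- 0.0293
  # three sites: complement product, cross-checked by enumerating the
  # eight branch outcomes of the three-site tree
  outcomes <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                          s3 = c(TRUE, FALSE))
  prob <- apply(outcomes, 1, function(o)
    prod(ifelse(o, p, 1 - p)))
  p_any <- sum(prob[apply(outcomes, 1, any)])
  expect_equal(total_frameshift_prob(p, 3), p_any, tolerance = 1e-12)
  expect_equal(total_frameshift_prob(p, 3), 1 - (1 - p)^3)
  # monotone in both arguments
  expect_true(all(diff(total_frameshift_prob(seq(0, 1, 0.1), 2)) >= 0))
  expect_true(all(diff(total_frameshift_prob(0.3, 1:6)) > 0))
  expect_error(total_frameshift_prob(0.5, 0), "integer")
})

test_that("energy fitting inverts the pause formula exactly", {
  fit <- fit_energies(0.75, 0.38, 0.20)
  expect_equal(unname(fit["delta_E"]), 3.0, tolerance = 0.05 / 3)
  expect_equal(unname(fit["delta_delta_ESD"]), 1.6, tolerance = 0.05 / 1.6)
  expect_equal(unname(fit["E_bp"]), 2.5, tolerance = 0.05 / 2.5)

  expect_equal(unname(fit_energies(0.5, 0.5, 0.5)),
               c(0, 0, 0), tolerance = 1e-12)

  # round trip: p_long_pause o fit_energies = identity on (0,1)^3
  set.seed(12)
  for (i in 1:20) {
    tr <- c(runif(1, 0.5, 5), runif(1, 0, 3), runif(1, 0, 4))
    ps <- c(p_long_pause(tr[1], tr[2], tr[3]),
            p_long_pause(tr[1], 0, tr[3]),
            p_long_pause(tr[1], tr[2], 0))
    fit <- fit_energies(ps[1], ps[2], ps[3])
    expect_lt(max(abs(fit - tr)), 1e-10)
    back <- c(p_long_pause(fit[1], fit[2], fit[3]),
              p_long_pause(fit[1], 0, fit[3]),
              p_long_pause(fit[1], fit[2], 0))
    expect_lt(max(abs(back - ps)), 1e-12)
  }
  expect_error(fit_energies(1, 0.38, 0.2), "strictly")
})

test_that("futile-barrier pinning reproduces the requested branch mass", {
  en <- wt_energies()
  b <- branch_probabilities(en)
  expect_equal(b$p_e1 + b$p_lp1, 0.57, tolerance = 1e-10)
  # and the published single-rotation split follows
  expect_equal(b$p_lp1, 0.43, tolerance = 0.005 / 0.43)
  expect_equal(b$p_e1, 0.14, tolerance = 0.005 / 0.14)
})

test_that("invalid energy inputs are rejected", {
  expect_error(energy_params(delta_E = NaN), "finite")
  expect_error(energy_params(delta_E = 3, delta_ESD2 = 2,
                             delta_ESD3 = 1), ">=")
  expect_error(energy_params(delta_E = 3, E_bp = -1), "E_bp")
  expect_error(p_long_pause(Inf, 0, 0), "finite")
})
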