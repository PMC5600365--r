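# The parameter-extraction chain: from the measured single-molecule
# aggregates (pause fractions, EF-G binding numbers and lifetimes,
# rotated-state dwells) to the kinetic constants of the model.

#' Observed single-molecule aggregates
#'
#' Container for the measured aggregates that drive the
#' parameter-extraction chain.  Defaults are the published values for
#' the dnaX constructs: per-codon pause probabilities 0.75 / 0.38 / 0.20
#' (wild type / no internal SD / no hairpin), four EF-G bindings per
#' codon at the obstructed non-slippery codon, 5.3 bindings and a 0.9-s
#' mean EF-G lifetime at the slippery codon, a 0.25-s EF-G lifetime at
#' the obstructed non-slippery codon, an 8-s rotated dwell at 80 nM
#' EF-G, a 12-s non-rotated dwell, two tRNA samplings per pause, a 30-s
#' sampled-tRNA lifetime, and the product `T_G * kb1_G = 0.5 /uM` from
#' the arrival-time fit.
#'
#' @param p_lp_wt,p_lp_no_sd,p_lp_no_hairpin per-codon long-pause
#'   probabilities of the three constructs.
#' @param n2_G_sd EF-G bindings per codon at the obstructed non-slippery
#'   codon.
#' @param n3_G EF-G bindings per cycle at the slippery codon.
#' @param t2_G_sd mean EF-G bound lifetime at the obstructed
#'   non-slippery codon (s).
#' @param t3_G mean EF-G bound lifetime at the slippery codon (s).
#' @param t_r1 mean rotated dwell at an unobstructed codon (s).
#' @param t_nr mean non-rotated dwell (s).
#' @param N_samplings mean tRNA samplings per long pause.
#' @param t_trna mean sampled-tRNA bound lifetime (s).
#' @param t_G_kb1_G fitted product of the long-pause EF-G lifetime and
#'   binding rate (1/uM).
#' @param conc_EFG EF-G concentration at which `t_r1` was measured (uM).
#' @param f_ut fraction of ribosomes taking the incomplete-translocation
#'   pathway (from the multi-pulse counts).
#' @param f_fs frameshifting fraction of the mutant with identical 0/-1
#'   A-site codons.
#' @param frac_half_sampling fraction of samplings visible when cognate
#'   and near-cognate arrivals are equally likely (0.5).
#' @return An object of class `"observed_aggregates"`.
#' @export
observed_aggregates <- function(p_lp_wt = 0.75, p_lp_no_sd = 0.38,
                                p_lp_no_hairpin = 0.20, n2_G_sd = 4,
                                n3_G = 5.3, t2_G_sd = 0.25, t3_G = 0.9,
                                t_r1 = 8, t_nr = 12, N_samplings = 2,
                                t_trna = 30, t_G_kb1_G = 0.5,
                                conc_EFG = 0.08, f_ut = 0.71,
                                f_fs = 0.49, frac_half_sampling = 0.5) {
  obs <- list(p_lp_wt = p_lp_wt, p_lp_no_sd = p_lp_no_sd,
              p_lp_no_hairpin = p_lp_no_hairpin, n2_G_sd = n2_G_sd,
              n3_G = n3_G, t2_G_sd = t2_G_sd, t3_G = t3_G, t_r1 = t_r1,
              t_nr = t_nr, N_samplings = N_samplings, t_trna = t_trna,
              t_G_kb1_G = t_G_kb1_G, conc_EFG = conc_EFG, f_ut = f_ut,
              f_fs = f_fs, frac_half_sampling = frac_half_sampling)
  for (nm in c("p_lp_wt", "p_lp_no_sd", "p_lp_no_hairpin", "f_ut",
               "f_fs", "frac_half_sampling"))
    if (obs[[nm]] < 0 || obs[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  for (nm in c("n2_G_sd", "n3_G", "t2_G_sd", "t3_G", "t_r1", "t_nr",
               "N_samplings", "t_trna", "t_G_kb1_G", "conc_EFG"))
    .check_positive(obs[[nm]], nm)
  structure(obs, class = "observed_aggregates")
}

#' Run the parameter-extraction chain
#'
#' Executes, in order, the arithmetic that converts the observed
#' aggregates into model parameters:
#'
#' 1. `p_e1_sd = 1 / n2_G_sd` - effective-translocation probability at
#'    the obstructed non-slippery codon (geometric binding count);
#' 2. `p_lp1` from `p_lp` via the transfer relation
#'    `p_e1 = p_e1_sd * (1 - p_lp1)` at the slippery codon, i.e.
#'    `p_lp1 = p_e1_sd * p_lp / (1 - (1 - p_e1_sd) * p_lp)`;
#' 3. `p_e1 = p_e1_sd * (1 - p_lp1)`;
#' 4. `n2_G = 1 / (p_e1 + p_lp1)` - canonical bindings at the slippery
#'    codon;
#' 5. `n_lp_G = (n3_G - n2_G) / p_lp` - EF-G bindings per long pause;
#' 6. `t_G` solving the occupancy-weighted lifetime mixture for the
#'    long-pause EF-G lifetime;
#' 7. `kb1_G = t_G_kb1_G / t_G` - EF-G binding rate to the long-paused
#'    rotated state;
#' 8. `kb_G = 1 / (t_r1 * conc_EFG)` - EF-G binding rate to the
#'    canonical rotated state;
#' 9. `k21_over_k20 = N_samplings - 1` - sampling dissociation ratio;
#' 10. the fitted branch energies from [fit_energies()].
#'
#' Steps whose inputs fall outside their feasible range are reported as
#' `NA` with a diagnostic note; the chain continues where possible.
#'
#' @param obs an [observed_aggregates()] object.
#' @return An object of class `"inference_report"`: a data.frame with
#'   columns `quantity`, `value`, `units` and `relation` (the defining
#'   arithmetic), with the diagnostics in `attr(, "notes")`.
#' @examples
#' rep <- run_inference_chain(observed_aggregates())
#' rep[rep$quantity %in% c("p_lp1", "p_e1", "t_G", "kb1_G"), ]
#' @export
run_inference_chain <- function(obs = observed_aggregates()) {
  stopifnot(inherits(obs, "observed_aggregates"))
  notes <- character()
  rows <- list()
  add <- function(quantity, value, units, relation)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, units = units,
      relation = relation, stringsAsFactors = FALSE)

  p_e1_sd <- 1 / obs$n2_G_sd
  add("p_e1_sd", p_e1_sd, "probability",
      "inverse of the EF-G binding count at the obstructed non-slippery codon")

  p_lp <- obs$p_lp_wt
  denom <- 1 - (1 - p_e1_sd) * p_lp
  p_lp1 <- p_e1_sd * p_lp / denom
  p_e1 <- p_e1_sd * (1 - p_lp1)
  add("p_lp1", p_lp1, "probability",
      "transfer of the non-slippery effective probability: p_e1 = p_e1_sd (1 - p_lp1)")
  add("p_e1", p_e1, "probability", "p_e1_sd * (1 - p_lp1)")

  n2_G <- if (p_e1 + p_lp1 > 0) 1 / (p_e1 + p_lp1) else NA_real_
  add("n2_G", n2_G, "bindings/codon",
      "geometric binding count with success probability p_e1 + p_lp1")

  n_lp_G <- tryCatch(solve_n_lp(obs$n3_G, n2_G, p_lp),
                     error = function(e) {
                       notes <<- c(notes, conditionMessage(e))
                       NA_real_
                     })
  add("n_lp_G", n_lp_G, "bindings/pause",
      "(n3_G - n2_G) / p_lp")

  t_G <- tryCatch(solve_t_G(obs$t3_G, n2_G, obs$t2_G_sd, p_lp, n_lp_G),
                  error = function(e) {
                    notes <<- c(notes, conditionMessage(e))
                    NA_real_
                  })
  add("t_G", t_G, "s",
      "occupancy-weighted lifetime mixture solved for the long-pause lifetime")

  kb1_G <- obs$t_G_kb1_G / t_G
  add("kb1_G", kb1_G, "1/(uM s)", "t_G_kb1_G / t_G")

  kb_G <- 1 / (obs$t_r1 * obs$conc_EFG)
  add("kb_G", kb_G, "1/(uM s)",
      "inverse rotated dwell over [EF-G] at the unobstructed codon")

  add("k21_over_k20", obs$N_samplings - 1, "ratio",
      "geometric sampling count minus one")

  en <- tryCatch(fit_energies(obs$p_lp_wt, obs$p_lp_no_sd,
                              obs$p_lp_no_hairpin),
                 error = function(e) {
                   notes <<- c(notes, conditionMessage(e))
                   c(delta_E = NA_real_, delta_delta_ESD = NA_real_,
                     E_bp = NA_real_)
                 })
  add("delta_E", en[["delta_E"]], "kBT",
      "logit inversion of the three pause probabilities")
  add("delta_delta_ESD", en[["delta_delta_ESD"]], "kBT",
      "logit inversion of the three pause probabilities")
  add("E_bp", en[["E_bp"]], "kBT",
      "logit inversion of the three pause probabilities")

  out <- do.call(rbind, rows)
  attr(out, "notes") <- notes
  class(out) <- c("inference_report", class(out))
  out
}

#' Non-frameshifted share of the incomplete-translocation pathway
#'
#' Difference between the fraction of ribosomes taking the
#' incomplete-translocation pathway (`f_ut`) and the frameshifted
#' fraction (`f_fs`): the ribosomes that paused but stayed in frame.
#'
#' @param f_ut incomplete-translocation fraction, in `[0, 1]`.
#' @param f_fs frameshifted fraction, `<= f_ut`.
#' @return The in-frame paused fraction `f_ut - f_fs`.
#' @examples
#' uncoupled_frame_budget(0.71, 0.49)  # 0.22
#' @export
uncoupled_frame_budget <- function(f_ut, f_fs) {
  .check_finite(f_ut, "f_ut")
  .check_finite(f_fs, "f_fs")
  if (f_ut < 0 || f_ut > 1 || f_fs < 0 || f_fs > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (f_ut < f_fs)
    stop("'f_ut' must be >= 'f_fs'", call. = FALSE)
  f_ut - f_fs
}

#' Probability of observing extra labelled-tRNA pulses
#'
#' Product of the incomplete-translocation fraction and the fraction of
#' samplings made by the visible (labelled) tRNA species; estimates the
#' probability of seeing more labelled pulses than the in-frame codons
#' alone produce.
#'
#' @param frac_uncoupled incomplete-translocation fraction, in `[0, 1]`.
#' @param sampling_fraction visible-sampling fraction, in `[0, 1]`.
#' @return A probability.
#' @examples
#' multi_pulse_probability(0.71, 0.5)  # ~0.355
#' @export
multi_pulse_probability <- function(frac_uncoupled, sampling_fraction) {
  .check_finite(frac_uncoupled, "frac_uncoupled")
  .check_finite(sampling_fraction, "sampling_fraction")
  if (frac_uncoupled < 0 || frac_uncoupled > 1 ||
      sampling_fraction < 0 || sampling_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  frac_uncoupled * sampling_fraction
}
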