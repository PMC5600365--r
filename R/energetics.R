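# Boltzmann branching at the unlocked pre-translocation state.
#
# After GTP hydrolysis and ribosomal unlocking, one reverse intersubunit
# rotation carries the ribosome over one of three free-energy barriers:
#   effective translocation (POST)  - unwind 3 bp and rupture the
#                                     SD-antiSD pairing over 3 nt;
#   futile translocation (FC)       - break the 50S E/P-site grip on the
#                                     two tRNAs;
#   incomplete +2 translocation (LP)- unwind 2 bp, slip the peptidyl-tRNA
#                                     anticodon by one codon, bend the
#                                     tRNA, rupture SD-antiSD over 2 nt.
# The outcome probabilities are the Boltzmann weights of the three
# barriers, normalized over the three channels.

.branch_weights <- function(w_lp, w_e, w_f) {
  tot <- w_lp + w_e + w_f
  p_lp1 <- w_lp / tot
  p_e1 <- w_e / tot
  p_f1 <- 1 - p_lp1 - p_e1
  p_lp <- if (p_lp1 + p_e1 > 0) p_lp1 / (p_lp1 + p_e1) else NA_real_
  structure(
    list(p_lp1 = p_lp1, p_e1 = p_e1, p_f1 = p_f1,
         p_lp = p_lp, p_nor = 1 - p_lp),
    class = "branch_probs")
}

#' Assemble branch probabilities directly
#'
#' Builds a `"branch_probs"` object from explicitly supplied
#' single-rotation outcome probabilities, for use where the three-way
#' split is known empirically rather than derived from energies.
#'
#' @param p_lp1 single-rotation probability of entering the long-paused
#'   state.
#' @param p_e1 single-rotation probability of effective translocation.
#' @param p_f1 single-rotation probability of futile translocation;
#'   defaults to the complement.
#' @return A `"branch_probs"` object.
#' @examples
#' branch_probs(p_lp1 = 0.43, p_e1 = 0.14)
#' @export
branch_probs <- function(p_lp1, p_e1, p_f1 = 1 - p_lp1 - p_e1) {
  for (p in c(p_lp1 = p_lp1, p_e1 = p_e1, p_f1 = p_f1))
    if (!is.numeric(p) || is.na(p) || p < -1e-12 || p > 1)
      stop("branch probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(p_lp1 + p_e1 + p_f1 - 1) > 1e-9)
    stop("branch probabilities must sum to 1", call. = FALSE)
  .branch_weights(p_lp1, p_e1, max(p_f1, 0))
}

#' @export
print.branch_probs <- function(x, ...) {
  cat(sprintf(
    "Single-rotation branch: P_LP(1) = %.4f  P_E(1) = %.4f  P_F(1) = %.4f\n",
    x$p_lp1, x$p_e1, x$p_f1))
  cat(sprintf("Per-codon long pause:   P_LP = %.4f  (P_Nor = %.4f)\n",
              x$p_lp, x$p_nor))
  invisible(x)
}

#' Single-rotation branch probabilities at the unlocked state
#'
#' Computes the probabilities that one reverse intersubunit rotation of
#' the unlocked ribosome ends in the long-paused state (`p_lp1`), in
#' effective translocation (`p_e1`) or in futile translocation (`p_f1`),
#' as Boltzmann weights of the corresponding barriers:
#'
#' \deqn{P_{LP}^{(1)} \propto e^{-(\Delta E + \Delta E_{SD}(2) + 2E_{bp})},\quad
#'       P_E^{(1)} \propto e^{-(\Delta E_{SD}(3) + 3E_{bp})},\quad
#'       P_F^{(1)} \propto e^{-E_{PE(50S)}}.}
#'
#' The per-codon pause probability `p_lp` conditions on the pause being
#' eventually resolved one way or the other,
#' `p_lp = p_lp1 / (p_lp1 + p_e1)`, and reduces to a logistic function of
#' `-(delta_E - delta_delta_ESD - E_bp)` in which the futile barrier
#' cancels (see [p_long_pause()]).
#'
#' @param energy an [energy_params()] object.
#' @return An object of class `"branch_probs"` with fields `p_lp1`,
#'   `p_e1`, `p_f1`, `p_lp`, `p_nor`.
#' @examples
#' wt <- energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6,
#'                     E_bp = 2.5)
#' branch_probabilities(wt)$p_lp  # ~0.75
#' @export
branch_probabilities <- function(energy) {
  stopifnot(inherits(energy, "energy_params"))
  b <- energy$beta
  w_lp <- exp(-b * (energy$delta_E + energy$delta_ESD2 + 2 * energy$E_bp))
  w_e <- exp(-b * (energy$delta_ESD3 + 3 * energy$E_bp))
  w_f <- exp(-b * energy$E_PE50S)
  .branch_weights(w_lp, w_e, w_f)
}

#' Per-codon probability of the long-paused rotated state
#'
#' The probability that an elongation cycle at the slippery codon ends in
#' the long-paused rotated state rather than in normal translation:
#'
#' \deqn{P_{LP} = \frac{e^{-(\Delta E - \Delta\Delta E_{SD} - E_{bp})}}
#'                     {e^{-(\Delta E - \Delta\Delta E_{SD} - E_{bp})} + 1}.}
#'
#' The futile-translocation barrier cancels from this ratio, so `p_lp`
#' depends only on the three energies shown and is independent of factor
#' concentrations.  It increases with hairpin stability (`E_bp`) and the
#' SD rupture-energy difference (`delta_delta_ESD`) and decreases with
#' the codon/tRNA penalty (`delta_E`).
#'
#' @param delta_E codon/tRNA free-energy cost (kBT).
#' @param delta_delta_ESD SD-antiSD rupture-energy difference (kBT).
#' @param E_bp per-base-pair hairpin unwinding energy (kBT).
#' @return The per-codon long-pause probability, in `[0, 1]`.
#' @examples
#' p_long_pause(3, 1.6, 2.5)  # wild type, ~0.75
#' p_long_pause(3, 0.0, 2.5)  # no internal SD, ~0.38
#' p_long_pause(3, 1.6, 0.0)  # no hairpin, ~0.20
#' @export
p_long_pause <- function(delta_E, delta_delta_ESD, E_bp) {
  for (v in list(delta_E = delta_E, delta_delta_ESD = delta_delta_ESD,
                 E_bp = E_bp))
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("energies must be finite numbers", call. = FALSE)
  stats::plogis(-(delta_E - delta_delta_ESD - E_bp))
}

#' Force-dependent branch probabilities
#'
#' Branch probabilities for a message with neither hairpin nor internal
#' SD sequence, with an external force `F` pulling the mRNA relative to
#' the 30S subunit.  Each nucleotide stepped against the force costs
#' `F * p` of work, so the effective-translocation barrier gains `3Fp`,
#' the incomplete-translocation barrier `2Fp`, and the per-codon pause
#' probability becomes a logistic function of `-(delta_E - Fp)`:
#' force promotes frameshifting.
#'
#' @param delta_E codon/tRNA free-energy cost (kBT).
#' @param E_PE50S futile-branch barrier (kBT); `Inf` suppresses the
#'   futile channel.  It cancels from `p_lp`.
#' @param ctx a [force_context()].
#' @return A `"branch_probs"` object.
#' @examples
#' branch_probabilities_force(3.5, Inf, force_context(F_pN = 0))$p_lp
#' @export
branch_probabilities_force <- function(delta_E, E_PE50S = Inf,
                                       ctx = force_context()) {
  .check_finite(delta_E, "delta_E")
  stopifnot(inherits(ctx, "force_context"))
  fp <- ctx$F_pN * ctx$p_nm / ctx$kBT_pN_nm  # work per nucleotide, kBT
  w_lp <- exp(-(delta_E + 2 * fp))
  w_e <- exp(-3 * fp)
  w_f <- exp(-E_PE50S)
  .branch_weights(w_lp, w_e, w_f)
}

#' Total frameshifting efficiency over tandem slippery sequences
#'
#' With a per-codon long-pause probability `p_lp` at each of `n`
#' identical slippery sequences, and every long pause committing the
#' ribosome to the -1 frame, the total frameshift probability is the
#' complement of escaping all `n` sites:
#' \deqn{P_{FS} = 1 - (1 - P_{LP})^n.}
#'
#' @param p_lp per-codon long-pause probability, in `[0, 1]`.
#' @param n number of tandem slippery sequences (integer >= 1).
#' @return Total frameshift probability.
#' @examples
#' total_frameshift_prob(0.029, 1)
#' total_frameshift_prob(0.029, 3)
#' @export
total_frameshift_prob <- function(p_lp, n) {
  if (!is.numeric(p_lp) || any(is.na(p_lp)) || any(p_lp < 0) ||
      any(p_lp > 1))
    stop("'p_lp' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1) ||
      any(n != round(n)))
    stop("'n' must be an integer >= 1", call. = FALSE)
  1 - (1 - p_lp)^n
}

#' Invert the pause-probability formula against three constructs
#'
#' Solves for the three free energies from the per-codon long-pause
#' probabilities of the wild-type message, the mutant without the
#' internal SD sequence (`delta_delta_ESD = 0`) and the mutant without
#' the downstream hairpin (`E_bp = 0`).  Because
#' `logit(p_lp) = -(delta_E - delta_delta_ESD - E_bp)` with the relevant
#' term dropped per construct, the three logits form a linear system
#' with the exact solution
#' `delta_delta_ESD = logit(p_wt) - logit(p_no_sd)`,
#' `E_bp = logit(p_wt) - logit(p_no_hairpin)`, and
#' `delta_E = E_bp - logit(p_no_sd)`.
#'
#' @param p_lp_wt per-codon pause probability of the wild type, in (0, 1).
#' @param p_lp_no_sd same for the construct lacking the internal SD.
#' @param p_lp_no_hairpin same for the construct lacking the hairpin.
#' @return A named numeric vector with components `delta_E`,
#'   `delta_delta_ESD` and `E_bp` (kBT).
#' @examples
#' fit_energies(0.75, 0.38, 0.20)  # ~ (3.0, 1.6, 2.5) kBT
#' @export
fit_energies <- function(p_lp_wt, p_lp_no_sd, p_lp_no_hairpin) {
  ps <- c(p_lp_wt = p_lp_wt, p_lp_no_sd = p_lp_no_sd,
          p_lp_no_hairpin = p_lp_no_hairpin)
  for (nm in names(ps)) {
    .check_finite(ps[[nm]], nm)
    if (ps[[nm]] <= 0 || ps[[nm]] >= 1)
      stop("'", nm, "' must lie strictly in (0, 1): the logit is infinite ",
           "at the boundary", call. = FALSE)
  }
  lw <- stats::qlogis(p_lp_wt)
  ls <- stats::qlogis(p_lp_no_sd)
  lh <- stats::qlogis(p_lp_no_hairpin)
  dd_esd <- lw - ls
  e_bp <- lw - lh
  d_e <- e_bp - ls
  c(delta_E = d_e, delta_delta_ESD = dd_esd, E_bp = e_bp)
}

#' Futile-branch barrier pinned to a target branch mass
#'
#' The 50S E/P-site binding energy `E_PE50S` has no direct measurement;
#' what is constrained is the combined single-rotation probability of the
#' two non-futile outcomes, `p_e1 + p_lp1` (0.57 at the wild-type
#' slippery site, from the observed EF-G binding numbers).  This helper
#' returns the `E_PE50S` for which `branch_probabilities()` reproduces a
#' requested `p_e1 + p_lp1`.
#'
#' @param energy an [energy_params()] object (its `E_PE50S` is ignored).
#' @param mass target value of `p_e1 + p_lp1`, strictly in (0, 1).
#' @return The implied `E_PE50S` (kBT).
#' @examples
#' wt <- energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6,
#'                     E_bp = 2.5)
#' e <- e_pe50s_for_branch_mass(wt, 0.57)
#' @export
e_pe50s_for_branch_mass <- function(energy, mass) {
  stopifnot(inherits(energy, "energy_params"))
  .check_finite(mass, "mass")
  if (mass <= 0 || mass >= 1)
    stop("'mass' must lie strictly in (0, 1)", call. = FALSE)
  b <- energy$beta
  w_lp <- exp(-b * (energy$delta_E + energy$delta_ESD2 + 2 * energy$E_bp))
  w_e <- exp(-b * (energy$delta_ESD3 + 3 * energy$E_bp))
  w_f <- (w_lp + w_e) * (1 - mass) / mass
  -log(w_f) / b
}
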