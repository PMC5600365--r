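# Parameter containers.  All free energies are in units of kBT (beta = 1),
# all first-order rates in 1/s, all bimolecular rates in 1/(uM s), all
# concentrations in uM, forces in pN and distances in nm.

.check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

.check_positive <- function(x, name) {
  .check_finite(x, name)
  if (x <= 0) stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}

#' Free-energy parameters of the three-way translocation branch
#'
#' Collects the free-energy differences (in units of the thermal energy
#' kBT) that govern the partitioning of the unlocked pre-translocation
#' ribosome between effective translocation, futile translocation and
#' incomplete (+2) translocation into the long-paused rotated state.
#'
#' The total codon/tRNA term `delta_E` is the sum of `delta_E_codon`
#' (shifting the peptidyl-tRNA anticodon from the second slippery codon
#' onto the first and breaking the E-site codon-anticodon contact) and
#' `delta_tRNA` (bending the P-site peptidyl-tRNA).  Either supply the
#' two components, or `delta_E` directly.  Likewise `delta_delta_ESD`
#' (the SD-antiSD rupture-energy difference between a three- and a
#' two-nucleotide ribosome displacement) may be given directly or as
#' `delta_ESD3 - delta_ESD2`.
#'
#' @param delta_E total codon/tRNA free-energy cost (kBT) of entering the
#'   long-paused state; defaults to `delta_E_codon + delta_tRNA` when the
#'   components are supplied.
#' @param delta_E_codon,delta_tRNA optional components of `delta_E` (kBT).
#' @param delta_ESD2 SD-antiSD free-energy change for a two-nucleotide
#'   displacement (kBT).
#' @param delta_ESD3 SD-antiSD free-energy change for a three-nucleotide
#'   displacement (kBT); must be >= `delta_ESD2`.
#' @param delta_delta_ESD difference `delta_ESD3 - delta_ESD2` (kBT);
#'   computed from the two SD terms when they are supplied.
#' @param E_bp free-energy cost of unwinding one base pair of the
#'   downstream hairpin (kBT); must be >= 0.
#' @param E_PE50S binding free energy of the 50S E and P sites for the two
#'   tRNAs (kBT), the barrier of the futile branch.  `Inf` suppresses the
#'   futile branch entirely.
#' @param beta inverse thermal energy; fixed at 1 because all energies are
#'   carried in kBT units.
#' @return An object of class `"energy_params"`.
#' @examples
#' energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6, E_bp = 2.5)
#' @export
energy_params <- function(delta_E = NULL, delta_E_codon = NULL,
                          delta_tRNA = NULL, delta_ESD2 = 0,
                          delta_ESD3 = NULL, delta_delta_ESD = NULL,
                          E_bp = 0, E_PE50S = Inf, beta = 1) {
  if (!identical(beta, 1) && !identical(beta, 1L))
    stop("'beta' is fixed at 1: energies are carried in kBT units",
         call. = FALSE)
  if (is.null(delta_E)) {
    if (is.null(delta_E_codon) || is.null(delta_tRNA))
      stop("supply 'delta_E' or both of its components", call. = FALSE)
    .check_finite(delta_E_codon, "delta_E_codon")
    .check_finite(delta_tRNA, "delta_tRNA")
    delta_E <- delta_E_codon + delta_tRNA
  } else {
    .check_finite(delta_E, "delta_E")
    if (!is.null(delta_E_codon) && !is.null(delta_tRNA) &&
        abs(delta_E - (delta_E_codon + delta_tRNA)) > 1e-12)
      stop("'delta_E' must equal delta_E_codon + delta_tRNA", call. = FALSE)
  }
  .check_finite(delta_ESD2, "delta_ESD2")
  if (is.null(delta_ESD3)) {
    if (is.null(delta_delta_ESD)) delta_delta_ESD <- 0
    .check_finite(delta_delta_ESD, "delta_delta_ESD")
    delta_ESD3 <- delta_ESD2 + delta_delta_ESD
  } else {
    .check_finite(delta_ESD3, "delta_ESD3")
    if (is.null(delta_delta_ESD)) {
      delta_delta_ESD <- delta_ESD3 - delta_ESD2
    } else if (abs(delta_delta_ESD - (delta_ESD3 - delta_ESD2)) > 1e-12) {
      stop("'delta_delta_ESD' must equal delta_ESD3 - delta_ESD2",
           call. = FALSE)
    }
  }
  if (delta_delta_ESD < 0)
    stop("'delta_ESD3' must be >= 'delta_ESD2'", call. = FALSE)
  if (!is.numeric(E_bp) || length(E_bp) != 1L || is.na(E_bp) || E_bp < 0)
    stop("'E_bp' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(E_PE50S) || length(E_PE50S) != 1L || is.na(E_PE50S))
    stop("'E_PE50S' must be a single number (possibly Inf)", call. = FALSE)
  structure(
    list(delta_E = delta_E, delta_E_codon = delta_E_codon,
         delta_tRNA = delta_tRNA, delta_ESD2 = delta_ESD2,
         delta_ESD3 = delta_ESD3, delta_delta_ESD = delta_delta_ESD,
         E_bp = E_bp, E_PE50S = E_PE50S, beta = 1),
    class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Translocation-branch free energies (kBT):\n")
  cat(sprintf("  delta_E = %.3g  delta_delta_ESD = %.3g  E_bp = %.3g  E_PE50S = %.3g\n",
              x$delta_E, x$delta_delta_ESD, x$E_bp, x$E_PE50S))
  invisible(x)
}

#' Mechanical context for force-dependent branching
#'
#' Describes an optical-trapping geometry in which an external force pulls
#' the mRNA relative to the 30S subunit, tilting the translocation
#' free-energy landscape by `F * p` per nucleotide stepped.
#'
#' @param F_pN external force on the mRNA (pN), >= 0.
#' @param p_nm distance per nucleotide (nm); default 0.34 nm.
#' @param n_slippery number of tandem slippery sequences on the message
#'   (integer >= 1).
#' @param kBT_pN_nm thermal energy in pN nm; default 4.1 (298 K).
#' @return An object of class `"force_context"`.
#' @export
force_context <- function(F_pN = 0, p_nm = 0.34, n_slippery = 1L,
                          kBT_pN_nm = 4.1) {
  .check_finite(F_pN, "F_pN")
  if (F_pN < 0) stop("'F_pN' must be >= 0", call. = FALSE)
  .check_positive(p_nm, "p_nm")
  .check_positive(kBT_pN_nm, "kBT_pN_nm")
  if (length(n_slippery) != 1L || is.na(n_slippery) ||
      n_slippery < 1 || n_slippery != round(n_slippery))
    stop("'n_slippery' must be an integer >= 1", call. = FALSE)
  structure(
    list(F_pN = F_pN, p_nm = p_nm, n_slippery = as.integer(n_slippery),
         kBT_pN_nm = kBT_pN_nm),
    class = "force_context")
}

#' Rate constants of tRNA sampling in the long-paused rotated state
#'
#' First-order rate constants of the aminoacyl-tRNA sampling sub-pathway
#' of the long-paused rotated state: the ternary complex binds, codon
#' recognition (`k20`) races against dissociation (`k21`); after
#' recognition, accommodation (`k22`) races against a second dissociation
#' channel (`k23`); the two resolution branches then proceed through
#' EF-G-dependent steps (`k24`/`k25` after dissociation, `k26`-`k28`
#' after accommodation).
#'
#' @param k20 codon-recognition rate (1/s).
#' @param k21 dissociation rate during codon recognition (1/s).
#' @param k22 accommodation rate (1/s).
#' @param k23 dissociation rate during accommodation (1/s).
#' @param k24 EF-G arrival rate on the post-dissociation branch (1/s);
#'   pseudo-first-order at the working EF-G concentration.
#' @param k25 reverse-rotation rate completing the post-dissociation
#'   branch (1/s).
#' @param k26 EF-G arrival rate on the post-accommodation branch (1/s);
#'   pseudo-first-order at the working EF-G concentration.
#' @param k27 unlocking rate on the post-accommodation branch (1/s).
#' @param k28 reverse-rotation rate completing the post-accommodation
#'   branch (1/s).
#' @return An object of class `"sampling_rates"`.
#' @seealso [calibrate_sampling_rates()] for defaults pinned to the
#'   observed sampling aggregates.
#' @export
sampling_rates <- function(k20, k21, k22, k23, k24 = 25, k25 = 25,
                           k26 = 0.0328, k27 = 35, k28 = 25) {
  vals <- list(k20 = k20, k21 = k21, k22 = k22, k23 = k23, k24 = k24,
               k25 = k25, k26 = k26, k27 = k27, k28 = k28)
  for (nm in names(vals)) .check_positive(vals[[nm]], nm)
  structure(vals, class = "sampling_rates")
}

#' Competition parameters for factor arrival at the long-paused state
#'
#' Parameters of the race between EF-G.GTP and the cognate ternary
#' complex for the open-30S long-paused rotated state.
#'
#' @param kb1_G EF-G.GTP binding rate to the long-paused rotated state
#'   (1/(uM s)).
#' @param kb1_TC ternary-complex binding rate to the long-paused rotated
#'   state (1/(uM s)).
#' @param T_G mean lifetime of EF-G bound to the long-paused rotated
#'   state (s).
#' @param conc_EFG EF-G.GTP concentration (uM).
#' @param conc_TC cognate ternary-complex concentration (uM).
#' @return An object of class `"arrival_params"`.
#' @export
arrival_params <- function(kb1_G = 0.41, kb1_TC = 0.16, T_G = 1.22,
                           conc_EFG = 0.08, conc_TC = 0.2) {
  .check_positive(kb1_G, "kb1_G")
  .check_positive(kb1_TC, "kb1_TC")
  .check_positive(T_G, "T_G")
  .check_finite(conc_EFG, "conc_EFG")
  if (conc_EFG < 0) stop("'conc_EFG' must be >= 0", call. = FALSE)
  .check_finite(conc_TC, "conc_TC")
  if (conc_TC < 0) stop("'conc_TC' must be >= 0", call. = FALSE)
  structure(
    list(kb1_G = kb1_G, kb1_TC = kb1_TC, T_G = T_G,
         conc_EFG = conc_EFG, conc_TC = conc_TC),
    class = "arrival_params")
}

#' Rate constants of the canonical elongation pathway
#'
#' First-order rates of the EF-G-driven steps of canonical translocation
#' plus the rates governing futile-translocation recycling, and the
#' bimolecular EF-G binding rate to the canonical rotated state.
#'
#' @param k4 reverse-rotation (unlocking-to-translocation) rate (1/s).
#' @param k6 post-translocation locking rate (1/s).
#' @param k7 EF-G.GDP release rate from the post-translocation state (1/s).
#' @param k14 rate of the futile non-rotated state re-entering the
#'   hybrid state (1/s).
#' @param kr EF-G.GDP release rate from the hybrid futile state (1/s).
#'   Only the inequality `1/k14 + 1/kr > 1/k4 + 1/k6 + 1/k7` is
#'   constrained by the observed EF-G lifetimes; the default satisfies it.
#' @param kb_G EF-G.GTP binding rate to the canonical rotated state
#'   (1/(uM s)).
#' @return An object of class `"elongation_rates"`.
#' @export
elongation_rates <- function(k4 = 35, k6 = 5, k7 = 20, k14 = 100,
                             kr = 2.5, kb_G = 1.5625) {
  vals <- list(k4 = k4, k6 = k6, k7 = k7, k14 = k14, kr = kr, kb_G = kb_G)
  for (nm in names(vals)) .check_positive(vals[[nm]], nm)
  structure(vals, class = "elongation_rates")
}

#' Parameters entering the rotated-state lifetime formulas
#'
#' Bundles everything the mean rotated-state lifetime expressions need:
#' binding rates, concentrations, the branch probabilities at the
#' unlocked state, and the sampling aggregates of the long-paused state.
#'
#' @param kb_G EF-G.GTP binding rate to the canonical rotated state
#'   (1/(uM s)).
#' @param kb1_G EF-G.GTP binding rate to the long-paused rotated state
#'   (1/(uM s)).
#' @param kb1_TC ternary-complex binding rate to the long-paused rotated
#'   state (1/(uM s)).
#' @param kr EF-G.GDP release rate from the hybrid futile state (1/s);
#'   may be `Inf` to drop the release term (lower-bound lifetimes).
#' @param conc_EFG EF-G.GTP concentration (uM).
#' @param conc_TC ternary-complex concentration (uM).
#' @param p_e1 single-rotation probability of effective translocation.
#' @param p_lp1 single-rotation probability of incomplete translocation
#'   into the long-paused state.
#' @param p_lp per-codon probability of the long pause,
#'   `p_lp1 / (p_lp1 + p_e1)`; computed from `p_e1` and `p_lp1` when not
#'   supplied.
#' @param N mean number of tRNA samplings per long pause.
#' @param T_tRNA mean lifetime of the sampled tRNA bound to the
#'   long-paused rotated state (s).
#' @param T_G mean EF-G lifetime bound to the long-paused rotated state (s).
#' @param T_NR mean non-rotated-state lifetime (s); only needed by
#'   [departure_time()].
#' @return An object of class `"lifetime_params"`.
#' @export
lifetime_params <- function(kb_G = 1.5625, kb1_G = 0.36, kb1_TC = 0.16,
                            kr = Inf, conc_EFG = 0.08, conc_TC = 1,
                            p_e1 = 0.14, p_lp1 = 0.43, p_lp = NULL,
                            N = 2, T_tRNA = 30, T_G = 0.5 / kb1_G,
                            T_NR = 12) {
  .check_positive(kb_G, "kb_G")
  .check_positive(kb1_G, "kb1_G")
  .check_positive(kb1_TC, "kb1_TC")
  if (!(length(kr) == 1L && is.numeric(kr) && !is.na(kr) && kr > 0))
    stop("'kr' must be > 0 (Inf allowed)", call. = FALSE)
  .check_positive(conc_EFG, "conc_EFG")
  .check_positive(conc_TC, "conc_TC")
  for (p in c(p_e1 = p_e1, p_lp1 = p_lp1))
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("branch probabilities must lie in [0, 1]", call. = FALSE)
  if (p_e1 + p_lp1 > 1 + 1e-12)
    stop("'p_e1' + 'p_lp1' must not exceed 1", call. = FALSE)
  if (is.null(p_lp)) {
    p_lp <- if (p_e1 + p_lp1 > 0) p_lp1 / (p_lp1 + p_e1) else 0
  } else if (p_lp1 + p_e1 > 0 &&
             abs(p_lp - p_lp1 / (p_lp1 + p_e1)) > 1e-8) {
    stop("'p_lp' is inconsistent with p_lp1 / (p_lp1 + p_e1)",
         call. = FALSE)
  }
  .check_positive(N, "N")
  .check_positive(T_tRNA, "T_tRNA")
  .check_positive(T_G, "T_G")
  .check_positive(T_NR, "T_NR")
  structure(
    list(kb_G = kb_G, kb1_G = kb1_G, kb1_TC = kb1_TC, kr = kr,
         conc_EFG = conc_EFG, conc_TC = conc_TC, p_e1 = p_e1,
         p_lp1 = p_lp1, p_lp = p_lp, N = N, T_tRNA = T_tRNA, T_G = T_G,
         T_NR = T_NR),
    class = "lifetime_params")
}
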