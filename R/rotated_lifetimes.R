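# Mean rotated-state lifetimes for the three site classes, the
# conditional lifetimes of pausing versus non-pausing ribosomes, and the
# deacylated-tRNA departure time.  All expressions neglect the backward
# rotated-to-non-rotated excursions that the FRET time resolution cannot
# see, and treat EF-G binding as the rate-limiting step it is at the low
# factor concentrations of the single-molecule experiments.

#' Mean rotated-state lifetime at an unobstructed codon
#'
#' With every binding translocating, the rotated dwell is set by the
#' EF-G.GTP arrival alone: `1 / (kb_G * [EF-G])`.  Inverse in `[EF-G]`,
#' independent of the ternary-complex concentration.
#'
#' @param kb_G EF-G.GTP binding rate to the canonical rotated state
#'   (1/(uM s)).
#' @param conc_EFG EF-G.GTP concentration (uM), > 0.
#' @return Mean rotated dwell (seconds).
#' @examples
#' t_r1(1.5625, 0.08)  # 8 s
#' @export
t_r1 <- function(kb_G, conc_EFG) {
  .check_positive(kb_G, "kb_G")
  if (!is.numeric(conc_EFG) || length(conc_EFG) != 1L ||
      is.na(conc_EFG) || conc_EFG <= 0)
    stop("infeasible: 'conc_EFG' must be > 0", call. = FALSE)
  1 / (kb_G * conc_EFG)
}

#' Mean rotated-state lifetime at an obstructed non-slippery codon
#'
#' Futile translocations recycle the ribosome through the hybrid state;
#' each futile round adds one EF-G.GDP release and one fresh EF-G.GTP
#' wait to the rotated dwell:
#' \deqn{T_{R2} = \frac{1}{P_E^{(1)} k_b^{(G)} [EF\mbox{-}G]} +
#'       \frac{1 - P_E^{(1)}}{P_E^{(1)} k_r}.}
#' With `kr = Inf` the release term drops and the value is a lower
#' bound.
#'
#' @param params a [lifetime_params()] object; uses `kb_G`, `kr`,
#'   `conc_EFG` and `p_e1`.
#' @return Mean rotated dwell (seconds).
#' @export
t_r2 <- function(params) {
  stopifnot(inherits(params, "lifetime_params"))
  if (params$p_e1 <= 0)
    stop("infeasible: 'p_e1' must be > 0", call. = FALSE)
  1 / (params$p_e1 * params$kb_G * params$conc_EFG) +
    (1 - params$p_e1) / (params$p_e1 * params$kr)
}

#' Departure time of the deacylated E-site tRNA
#'
#' The deacylated tRNA leaves one full elongation cycle after its
#' arrival: a non-rotated period `T_NR` followed by the rotated dwell of
#' the obstructed codon, `departure = T_NR + t_r2(params)`.  With
#' `kr = Inf` (the default) the value is a lower bound.
#'
#' @param params a [lifetime_params()] object; uses `T_NR` plus the
#'   [t_r2()] inputs.
#' @return Mean departure time (seconds).
#' @examples
#' departure_time(lifetime_params(p_e1 = 0.25, conc_EFG = 0.08))  # >= 44 s
#' @export
departure_time <- function(params) {
  stopifnot(inherits(params, "lifetime_params"))
  params$T_NR + t_r2(params)
}

#' Mean rotated-state lifetime at the slippery site
#'
#' Adds the long-pause excursion to the obstructed-codon dwell.  With
#' probability `p_lp` the cycle detours through the long-paused rotated
#' state, where `N` tRNA samplings (each preceded by a factor-competition
#' wait `tau` and lasting `T_tRNA` on average) and one final EF-G wait
#' accumulate:
#' \deqn{T_{R3} = \Big[\frac{1}{k_b^{(G)}(P_E^{(1)} + P_{LP}^{(1)})} +
#'   \frac{P_{LP}}{k_{b1}^{(G)}}\Big]\frac{1}{[EF\mbox{-}G]} +
#'   \frac{1 - P_E^{(1)} - P_{LP}^{(1)}}{(P_E^{(1)} + P_{LP}^{(1)}) k_r} +
#'   P_{LP} N T_{tRNA} +
#'   \frac{P_{LP} N (1 + T^{(G)} k_{b1}^{(G)} [EF\mbox{-}G])}
#'        {k_{b1}^{(TC)} [TC]}.}
#' Unlike the non-slippery dwell this is not inverse in `[EF-G]`: the
#' sampling and ternary-complex terms persist at saturating EF-G.
#'
#' The EF-G.GDP-release term (the `kr` term) is negligible at the low
#' factor concentrations of the single-molecule experiments and is
#' dropped by default (`params$kr = Inf`); supply a finite `kr` to
#' include it.
#'
#' @param params a [lifetime_params()] object.
#' @return Mean rotated dwell (seconds).
#' @export
t_r3 <- function(params) {
  stopifnot(inherits(params, "lifetime_params"))
  ps <- params$p_e1 + params$p_lp1
  if (ps <= 0)
    stop("infeasible: 'p_e1' + 'p_lp1' must be > 0", call. = FALSE)
  with(params, {
    (1 / (kb_G * ps) + p_lp / kb1_G) / conc_EFG +
      (1 - ps) / (ps * kr) +
      p_lp * N * T_tRNA +
      p_lp * N * (1 + T_G * kb1_G * conc_EFG) / (kb1_TC * conc_TC)
  })
}

#' Rotated dwell of ribosomes that enter the long pause
#'
#' Conditional mean rotated-state lifetime of the sub-population whose
#' cycle detours through the long-paused rotated state: the common
#' pre-branch terms plus the full sampling excursion (taken with
#' probability one rather than `p_lp`).
#'
#' @param params a [lifetime_params()] object.
#' @return Conditional mean rotated dwell (seconds).
#' @export
t_r3_lp <- function(params) {
  stopifnot(inherits(params, "lifetime_params"))
  ps <- params$p_e1 + params$p_lp1
  if (ps <= 0)
    stop("infeasible: 'p_e1' + 'p_lp1' must be > 0", call. = FALSE)
  with(params, {
    1 / (ps * kb_G * conc_EFG) + (1 - ps) / (ps * kr) +
      1 / (kb1_G * conc_EFG) + N * T_tRNA +
      N * (1 + T_G * kb1_G * conc_EFG) / (kb1_TC * conc_TC)
  })
}

#' Rotated dwell of ribosomes that avoid the long pause
#'
#' Conditional mean rotated-state lifetime of the sub-population that
#' translocates without the long pause; identical to [t_r2()] with the
#' effective probability `p_e1 + p_lp1`.
#'
#' @param params a [lifetime_params()] object.
#' @return Conditional mean rotated dwell (seconds).
#' @export
t_r3_nl <- function(params) {
  stopifnot(inherits(params, "lifetime_params"))
  ps <- params$p_e1 + params$p_lp1
  if (ps <= 0)
    stop("infeasible: 'p_e1' + 'p_lp1' must be > 0", call. = FALSE)
  with(params, {
    1 / (ps * kb_G * conc_EFG) + (1 - ps) / (ps * kr)
  })
}
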