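# tRNA sampling statistics in the long-paused rotated state.
#
# Within the long pause the open-30S rotated ribosome is sampled
# repeatedly by the cognate ternary complex.  Each sampling either fails
# during codon recognition (rate k21 against k20), fails during
# accommodation (k23 against k22), or completes.  Samplings repeat until
# one passes codon recognition, giving geometric sampling numbers; EF-G
# competes with the ternary complex for the open state in between.

#' Dissociation probability during codon recognition
#'
#' Probability that a sampled aminoacyl-tRNA dissociates before codon
#' recognition completes, from the race of two exponential clocks:
#' `k21 / (k21 + k20)`.
#'
#' @param rates a [sampling_rates()] object.
#' @return A probability.
#' @export
p_dissoc_pre <- function(rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  rates$k21 / (rates$k21 + rates$k20)
}

#' Mean number of tRNA samplings per long pause
#'
#' Samplings repeat until one survives codon recognition, so the count is
#' geometric with success probability `1 - p_dissoc_pre(rates)` and mean
#' `(k20 + k21) / k20`.  The mean depends only on `k20` and `k21`, not on
#' any factor concentration.
#'
#' @param rates a [sampling_rates()] object.
#' @return Mean sampling count (>= 1).
#' @export
mean_samplings <- function(rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  (rates$k20 + rates$k21) / rates$k20
}

#' Dissociation probability during accommodation
#'
#' Probability that the recognized tRNA dissociates before accommodation
#' completes: `k23 / (k23 + k22)`.
#'
#' @param rates a [sampling_rates()] object.
#' @return A probability.
#' @export
p_dissoc_post <- function(rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  rates$k23 / (rates$k23 + rates$k22)
}

#' Bound-lifetime components of the sampled tRNA
#'
#' Returns the three lifetime contributions entering the mean bound
#' lifetime of the sampled tRNA:
#' * `T1` - the codon-recognition-stage dissociation term, the exact
#'   value of the defining double integral
#'   \eqn{\int_0^\infty dt\, f_{2\to3}(t) \int_0^t dt'\, t' g_{2\to3}(t')}
#'   over the exponential densities `f = k20 exp(-k20 t)`,
#'   `g = k21 exp(-k21 t)`, which evaluates to
#'   `k21 / (k20 + k21)^2`.  Note this is the joint expectation
#'   `E[t 1{dissociation first}]`, i.e. it carries the dissociation
#'   probability inside it (it is not a conditional mean).
#' * `T2` - the accommodation-stage analogue,
#'   `1/k20 + k23 / (k22 + k23)^2`.
#' * `T3` - the full pass-through time
#'   `1/k20 + 1/k22 + 1/k26 + 1/k27 + 1/k28`.
#'
#' @param rates a [sampling_rates()] object.
#' @return A list with components `T1`, `T2`, `T3` (seconds).
#' @export
trna_lifetime_components <- function(rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  with(rates, list(
    T1 = k21 / (k20 + k21)^2,
    T2 = 1 / k20 + k23 / (k22 + k23)^2,
    T3 = 1 / k20 + 1 / k22 + 1 / k26 + 1 / k27 + 1 / k28))
}

#' Mean lifetime of the sampled tRNA bound to the long-paused state
#'
#' Combines the lifetime components into the mean bound lifetime per
#' sampling.  Three methods are provided:
#'
#' * `"integral"` (default) - the components of
#'   [trna_lifetime_components()] combined as
#'   `((N - 1) T1 + P34 T2 + (1 - P34) T3) / N`, with
#'   `N = mean_samplings(rates)` and `P34 = p_dissoc_post(rates)`.  `T1`
#'   and the dissociation part of `T2` enter unconditioned, exactly as
#'   the defining integrals produce them.
#' * `"expanded"` - the same quantity written out directly in the rate
#'   constants; agrees with `"integral"` to machine precision and is kept
#'   as an independent algebraic route.
#' * `"markov"` - the exact mean dwell of a tRNA pulse in the
#'   continuous-time Markov chain of the sampling sub-pathway:
#'   `1/(k20 + k21) + (1 - P23) (1/(k22 + k23) +
#'    (1 - P34)(1/k26 + 1/k27 + 1/k28))`.
#'   This is the quantity a dwell-time histogram of simulated (or
#'   measured) pulses estimates.  It differs from `"integral"` because
#'   the integral-defined combination mixes joint and marginal
#'   expectations; see the package vignette for the distinction.
#'
#' All methods are independent of the EF-G and ternary-complex
#' concentrations except through the pseudo-first-order `k26` (whose
#' weight `1 - P34` is small in the operating regime `k23 >> k22`).
#'
#' @param rates a [sampling_rates()] object.
#' @param method one of `"integral"`, `"expanded"`, `"markov"`.
#' @return Mean bound lifetime (seconds).
#' @export
mean_trna_lifetime <- function(rates,
                               method = c("integral", "expanded",
                                          "markov")) {
  stopifnot(inherits(rates, "sampling_rates"))
  method <- match.arg(method)
  if (method == "integral") {
    comp <- trna_lifetime_components(rates)
    n <- mean_samplings(rates)
    p34 <- p_dissoc_post(rates)
    ((n - 1) * comp$T1 + p34 * comp$T2 + (1 - p34) * comp$T3) / n
  } else if (method == "expanded") {
    with(rates, {
      term1 <- 1 / (k20 + k21) - k20 * (k20 + 2 * k21) / (k20 + k21)^3
      w_diss <- k20 * k23 / ((k20 + k21) * (k22 + k23))
      w_pass <- k20 * k22 / ((k20 + k21) * (k22 + k23))
      t2 <- 1 / k20 + 1 / k23 -
        k22 * (k22 + 2 * k23) / (k23 * (k22 + k23)^2)
      t3 <- 1 / k20 + 1 / k22 + 1 / k26 + 1 / k27 + 1 / k28
      term1 + w_diss * t2 + w_pass * t3
    })
  } else {
    with(rates, {
      p23 <- k21 / (k20 + k21)
      p34 <- k23 / (k22 + k23)
      1 / (k20 + k21) + (1 - p23) *
        (1 / (k22 + k23) + (1 - p34) * (1 / k26 + 1 / k27 + 1 / k28))
    })
  }
}

#' Calibrate the sampling rates to the observed aggregates
#'
#' Builds a [sampling_rates()] set reproducing the measured sampling
#' aggregates of the long-paused state: mean sampling number `N` (which
#' fixes `k21 / k20 = N - 1`) and mean bound lifetime `T_tRNA` (which
#' fixes the overall time scale, solved numerically).  The accommodation
#' stage is pinned by the observation that almost every recognized tRNA
#' dissociates again (`k23 >> k22`), implemented as a fixed ratio
#' `k23 = ratio_k23_k22 * k22` with `k22 = k20`.
#'
#' @param T_tRNA target mean bound lifetime (s); default 30 s.
#' @param N target mean sampling number; default 2.
#' @param ratio_k23_k22 ratio enforcing the dominant dissociation channel;
#'   default 50.
#' @param k26,k27,k28 pass-through branch rates (1/s); `k26` defaults to
#'   the pseudo-first-order EF-G arrival rate at 0.08 uM EF-G.
#' @param method lifetime definition used for the calibration target;
#'   passed to [mean_trna_lifetime()].
#' @return A calibrated [sampling_rates()] object.
#' @examples
#' r <- calibrate_sampling_rates()
#' mean_samplings(r)                 # 2
#' mean_trna_lifetime(r)             # 30
#' @export
calibrate_sampling_rates <- function(T_tRNA = 30, N = 2,
                                     ratio_k23_k22 = 50,
                                     k26 = 0.41 * 0.08, k27 = 35,
                                     k28 = 25, method = "integral") {
  .check_positive(T_tRNA, "T_tRNA")
  if (N <= 1) stop("'N' must be > 1", call. = FALSE)
  .check_positive(ratio_k23_k22, "ratio_k23_k22")
  f <- function(k20) {
    r <- sampling_rates(k20 = k20, k21 = (N - 1) * k20, k22 = k20,
                        k23 = ratio_k23_k22 * k20, k26 = k26, k27 = k27,
                        k28 = k28)
    mean_trna_lifetime(r, method = method) - T_tRNA
  }
  k20 <- stats::uniroot(f, c(1e-6, 1e3), tol = 1e-12)$root
  sampling_rates(k20 = k20, k21 = (N - 1) * k20, k22 = k20,
                 k23 = ratio_k23_k22 * k20, k26 = k26, k27 = k27,
                 k28 = k28)
}

#' Probability that EF-G binds the open long-paused state first
#'
#' EF-G.GTP and the cognate ternary complex race for the open-30S
#' long-paused rotated state; EF-G wins with probability equal to its
#' share of the total binding flux.
#'
#' @param params an [arrival_params()] object.
#' @return A probability.
#' @export
p_efg_binding <- function(params) {
  stopifnot(inherits(params, "arrival_params"))
  flux_g <- params$kb1_G * params$conc_EFG
  flux_tc <- params$kb1_TC * params$conc_TC
  if (flux_g + flux_tc == 0)
    stop("both binding fluxes are zero", call. = FALSE)
  flux_g / (flux_g + flux_tc)
}

#' Mean number of EF-G bindings before the ternary complex arrives
#'
#' Geometric count of EF-G visits to the open long-paused state before a
#' ternary complex binds: `P_G / (1 - P_G)` with `P_G` from
#' [p_efg_binding()].
#'
#' @param params an [arrival_params()] object.
#' @return Mean EF-G visit count (>= 0).
#' @export
mean_efg_visits <- function(params) {
  stopifnot(inherits(params, "arrival_params"))
  if (params$conc_TC == 0)
    stop("infeasible: with conc_TC = 0 the ternary complex never arrives",
         call. = FALSE)
  p <- p_efg_binding(params)
  p / (1 - p)
}

#' Mean arrival time of the ternary complex at the long-paused state
#'
#' Mean waiting time from the opening of the long-paused rotated state to
#' the productive ternary-complex binding, counting the EF-G visits (mean
#' number `mean_efg_visits`, each occupying the state for `T_G` on
#' average) that intervene:
#' \deqn{\tau = \frac{1 + T^{(G)} k_{b1}^{(G)} [EF\mbox{-}G]}
#'                   {k_{b1}^{(TC)} [TC]}.}
#' Affine increasing in `[EF-G]`, inverse in `[TC]`.
#'
#' @param params an [arrival_params()] object.
#' @return Mean arrival time (seconds).
#' @examples
#' mean_arrival_time(arrival_params(conc_EFG = 0.08, conc_TC = 0.2))
#' @export
mean_arrival_time <- function(params) {
  stopifnot(inherits(params, "arrival_params"))
  if (params$conc_TC == 0)
    stop("infeasible: with conc_TC = 0 the arrival time is infinite",
         call. = FALSE)
  (1 + params$T_G * params$kb1_G * params$conc_EFG) /
    (params$kb1_TC * params$conc_TC)
}
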