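# EF-G binding numbers and bound lifetimes per codon for the three site
# classes, together with the inversions used to extract the long-pause
# EF-G statistics from measured per-codon aggregates.

#' Mean EF-G bound lifetime at an unobstructed codon
#'
#' At a codon with neither SD-antiSD interaction nor downstream duplex,
#' every EF-G binding translocates, and the bound lifetime is the sum of
#' the exponential means of the reverse rotation, locking and
#' EF-G.GDP-release steps: `1/k4 + 1/k6 + 1/k7`.
#'
#' @param rates an [elongation_rates()] object.
#' @return Mean bound lifetime (seconds).
#' @examples
#' efg_lifetime_simple(elongation_rates())  # 0.28 s
#' @export
efg_lifetime_simple <- function(rates) {
  stopifnot(inherits(rates, "elongation_rates"))
  1 / rates$k4 + 1 / rates$k6 + 1 / rates$k7
}

#' Mean number of EF-G bindings per codon
#'
#' EF-G bindings repeat until one produces an effective translocation, so
#' the count is geometric: `1 / p_effective`.  At a non-slippery site
#' `p_effective` is the effective-translocation probability `p_e1`; at
#' the slippery site the long pause also ends the canonical binding
#' series, so `p_effective = p_e1 + p_lp1`.
#'
#' @param p_effective probability that one binding ends the series, in
#'   (0, 1].
#' @return Mean binding count (>= 1).
#' @examples
#' n_efg_per_codon(0.25)  # 4
#' @export
n_efg_per_codon <- function(p_effective) {
  .check_finite(p_effective, "p_effective")
  if (p_effective <= 0 || p_effective > 1)
    stop("infeasible: 'p_effective' must lie in (0, 1]", call. = FALSE)
  1 / p_effective
}

#' Mean EF-G bound lifetime at an obstructed non-slippery codon
#'
#' With the SD-antiSD interaction and downstream hairpin present, only a
#' fraction of bindings translocate; each futile binding occupies the
#' ribosome for the futile-state transit plus EF-G.GDP release,
#' `1/k14 + 1/kr`.  The per-binding mean is the weighted average
#' \deqn{T_2^{(G)} = \frac{(N_2^{(G)} - 1)(1/k_{14} + 1/k_r) +
#'   T_1^{(G)}}{N_2^{(G)}}.}
#'
#' @param rates an [elongation_rates()] object.
#' @param n2_G mean number of EF-G bindings per codon (>= 1).
#' @return Mean bound lifetime (seconds); exceeds
#'   [efg_lifetime_simple()] whenever `1/k14 + 1/kr` does.
#' @export
efg_lifetime_sd <- function(rates, n2_G) {
  stopifnot(inherits(rates, "elongation_rates"))
  .check_finite(n2_G, "n2_G")
  if (n2_G < 1) stop("'n2_G' must be >= 1", call. = FALSE)
  t1 <- efg_lifetime_simple(rates)
  ((n2_G - 1) * (1 / rates$k14 + 1 / rates$kr) + t1) / n2_G
}

#' Mean EF-G bindings per elongation cycle at the slippery site
#'
#' Adds the long-pause EF-G visits to the canonical binding count:
#' `N3 = N2 + p_lp * n_lp_G`, where `n_lp_G` is the mean number of EF-G
#' bindings to the long-paused rotated state per pause.
#'
#' @param n2_G canonical binding count (from [n_efg_per_codon()] with
#'   `p_e1 + p_lp1`).
#' @param p_lp per-codon long-pause probability.
#' @param n_lp_G mean EF-G bindings per long pause.
#' @return Mean total binding count.
#' @export
n_efg_slippery <- function(n2_G, p_lp, n_lp_G) {
  .check_finite(n2_G, "n2_G")
  .check_finite(p_lp, "p_lp")
  .check_finite(n_lp_G, "n_lp_G")
  n2_G + p_lp * n_lp_G
}

#' Long-pause EF-G binding number from the per-codon total
#'
#' Inverts [n_efg_slippery()]: `n_lp_G = (n3_G - n2_G) / p_lp`.
#'
#' @param n3_G observed total EF-G bindings per cycle at the slippery
#'   site.
#' @param n2_G canonical binding count.
#' @param p_lp per-codon long-pause probability (> 0).
#' @return Mean EF-G bindings per long pause.
#' @examples
#' solve_n_lp(5.3, 1.75, 0.75)  # ~4.73
#' @export
solve_n_lp <- function(n3_G, n2_G, p_lp) {
  .check_finite(n3_G, "n3_G")
  .check_finite(n2_G, "n2_G")
  .check_finite(p_lp, "p_lp")
  if (p_lp <= 0)
    stop("infeasible: 'p_lp' must be > 0 to invert", call. = FALSE)
  (n3_G - n2_G) / p_lp
}

#' Mean EF-G bound lifetime at the slippery site
#'
#' Occupancy-weighted mean over the canonical bindings (mean lifetime
#' `t2_G`) and the long-pause bindings (mean lifetime `t_G`):
#' \deqn{T_3^{(G)} = \frac{N_2^{(G)} T_2^{(G)} +
#'   P_{LP} N_{LP}^{(G)} T^{(G)}}{N_2^{(G)} + P_{LP} N_{LP}^{(G)}}.}
#'
#' @param n2_G canonical binding count.
#' @param t2_G canonical per-binding lifetime (s).
#' @param p_lp per-codon long-pause probability.
#' @param n_lp_G mean EF-G bindings per long pause.
#' @param t_G mean EF-G lifetime on the long-paused rotated state (s).
#' @return Mean bound lifetime (seconds).
#' @export
efg_lifetime_slippery <- function(n2_G, t2_G, p_lp, n_lp_G, t_G) {
  for (v in c(n2_G = n2_G, t2_G = t2_G, p_lp = p_lp, n_lp_G = n_lp_G,
              t_G = t_G))
    .check_finite(v, "efg_lifetime_slippery argument")
  w <- n2_G + p_lp * n_lp_G
  if (w <= 0) stop("degenerate weights", call. = FALSE)
  (n2_G * t2_G + p_lp * n_lp_G * t_G) / w
}

#' Long-pause EF-G lifetime from the slippery-site mean
#'
#' Inverts [efg_lifetime_slippery()] for the long-pause per-binding
#' lifetime `t_G`.
#'
#' @param t3_G observed mean EF-G lifetime at the slippery site (s).
#' @param n2_G canonical binding count.
#' @param t2_G canonical per-binding lifetime (s).
#' @param p_lp per-codon long-pause probability.
#' @param n_lp_G mean EF-G bindings per long pause.
#' @return Mean EF-G lifetime on the long-paused rotated state (s).
#' @examples
#' solve_t_G(0.9, 1.75, 0.25, 0.75, 4.73)  # ~1.22 s
#' @export
solve_t_G <- function(t3_G, n2_G, t2_G, p_lp, n_lp_G) {
  for (v in c(t3_G = t3_G, n2_G = n2_G, t2_G = t2_G, p_lp = p_lp,
              n_lp_G = n_lp_G))
    .check_finite(v, "solve_t_G argument")
  denom <- p_lp * n_lp_G
  if (denom <= 0)
    stop("infeasible: long-pause occupancy is zero", call. = FALSE)
  (t3_G * (n2_G + denom) - n2_G * t2_G) / denom
}
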