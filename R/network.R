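# Declarative state networks of the elongation pathway.
#
# Three site classes share a canonical core (EF-G binding to the rotated
# pre-translocation complex, unlocking, reverse rotation, ternary-complex
# delivery, peptidyl transfer).  The duplex network adds the futile
# branch (FC/FH recycling); the slippery network further adds the
# incomplete +2 translocation into the long-paused rotated state and its
# tRNA/EF-G sampling sub-pathway.
#
# The three-way outcome of the reverse intersubunit rotation is carried
# by an instantaneous branch state fed with the Boltzmann probabilities
# of the energetics module (outcome probabilities are what the model
# specifies); a rate-based rendering of the same branch is available for
# sensitivity checks.  The unlocking delay (1/k4) is charged to the
# effective-translocation path so that per-binding EF-G occupancies of
# futile rounds are exactly the futile-state transit plus release, the
# granularity at which the closed-form lifetime algebra operates.

.SITE_TYPES <- c("single_stranded", "duplex_nonslippery", "duplex_slippery")

#' Build the elongation state network for a site class
#'
#' Assembles the labelled continuous-time Markov chain of one elongation
#' cycle (from the post-peptidyl-transfer state back to itself) for a
#' single-stranded message, a duplex non-slippery codon, or the duplex
#' slippery codon.  Bimolecular binding steps are folded to
#' pseudo-first-order rates at the supplied concentrations.  The EF-G
#' arrival steps that resolve the long pause (`k24`, `k26` of the
#' sampling sub-pathway) are set to `kb1_G * conc_EFG`.
#'
#' @param site_type one of `"single_stranded"`, `"duplex_nonslippery"`,
#'   `"duplex_slippery"`.
#' @param branch a `"branch_probs"` object giving the three-way outcome
#'   probabilities at the unlocked state (e.g. from
#'   [branch_probabilities()] or [branch_probabilities_force()]).
#'   Ignored for `site_type = "single_stranded"` (the outcome is certain);
#'   for `"duplex_nonslippery"` its `p_lp1` must be 0.
#' @param elong an [elongation_rates()] object.
#' @param sampling a [sampling_rates()] object (slippery sites only).
#' @param arrival an [arrival_params()] object supplying `kb1_G`,
#'   `kb1_TC` and `T_G` (its concentrations are ignored in favour of the
#'   arguments below).
#' @param conc_EFG EF-G.GTP concentration (uM).
#' @param conc_TC concentration of the ternary complex cognate to the
#'   sampled codon of the long-paused state (uM).
#' @param conc_TC_next concentration of the ternary complex delivering
#'   the next canonical aminoacyl-tRNA (uM).
#' @param kb_TC_nr ternary-complex binding rate to the open non-rotated
#'   post-translocation state (1/(uM s)); uncalibrated, defaulted so the
#'   mean non-rotated lifetime is about 12 s at 1 uM.
#' @param k01 forward-rotation rate of the labile pre-translocation
#'   complex (1/s).
#' @param k16 rate of the long-paused non-rotated state re-entering the
#'   rotated conformation (1/s); defaulted to the reverse-rotation rate
#'   `k4`, after which EF-G.GDP release proceeds through the same `k6`,
#'   `k7` steps as on the effective-translocation path, so a
#'   pause-entering EF-G binding occupies the ribosome for the same mean
#'   time as a translocating one.
#' @param k_codon lumped rate of each fast canonical decoding step
#'   (codon recognition through peptidyl transfer) (1/s).
#' @param p_frame0 probability that the tRNA sampled in the long pause is
#'   cognate to the 0-frame codon, restoring the reading frame on
#'   recognition; 0 reproduces the wild-type slippery message, where
#'   every long pause commits to the -1 frame.
#' @param branch_mode `"probabilistic"` resolves the three-way branch as
#'   an instantaneous choice with the supplied probabilities (the model's
#'   specification); `"rates"` renders it as three competing exponential
#'   channels with rates `branch_rate * probability` for sensitivity
#'   checks.
#' @param branch_rate total branch rate (1/s) used by
#'   `branch_mode = "rates"`.
#' @return An object of class `"state_network"`.
#' @examples
#' wt <- energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6,
#'                     E_bp = 2.5)
#' wt$E_PE50S <- e_pe50s_for_branch_mass(wt, 0.57)
#' net <- build_network("duplex_slippery", branch_probabilities(wt))
#' @export
build_network <- function(site_type = .SITE_TYPES,
                          branch = NULL,
                          elong = elongation_rates(),
                          sampling = calibrate_sampling_rates(),
                          arrival = arrival_params(),
                          conc_EFG = 0.08, conc_TC = 0.2,
                          conc_TC_next = 1, kb_TC_nr = 0.085,
                          k01 = 25, k16 = 35, k_codon = 50,
                          p_frame0 = 0,
                          branch_mode = c("probabilistic", "rates"),
                          branch_rate = 1000) {
  site_type <- match.arg(site_type)
  branch_mode <- match.arg(branch_mode)
  stopifnot(inherits(elong, "elongation_rates"),
            inherits(arrival, "arrival_params"))
  .check_positive(conc_EFG, "conc_EFG")
  .check_positive(conc_TC_next, "conc_TC_next")
  for (v in c(kb_TC_nr = kb_TC_nr, k01 = k01, k16 = k16,
              k_codon = k_codon))
    .check_positive(v, names(v))
  if (p_frame0 < 0 || p_frame0 >= 1)
    stop("'p_frame0' must lie in [0, 1)", call. = FALSE)

  if (site_type == "single_stranded") {
    branch <- .branch_weights(0, 1, 0)
    branch$p_lp <- 0; branch$p_nor <- 1
  }
  if (is.null(branch))
    stop("configuration error: 'branch' probabilities are required for ",
         site_type, call. = FALSE)
  stopifnot(inherits(branch, "branch_probs"))
  if (site_type == "duplex_nonslippery" && branch$p_lp1 > 1e-12)
    stop("configuration error: a non-slippery duplex site has no ",
         "long-pause channel (p_lp1 must be 0)", call. = FALSE)

  st <- function(name, rotated, efg, trna = "none")
    data.frame(name = name, rotated = rotated, efg = efg, trna = trna,
               stringsAsFactors = FALSE)
  states <- rbind(
    st("C0", FALSE, FALSE),
    st("H0", TRUE, FALSE),
    st("H2", TRUE, TRUE),    # instantaneous branch: unlocked, pre-rotation
    st("H2E", TRUE, TRUE),   # committed to effective translocation
    st("POST", FALSE, TRUE),
    st("P1", FALSE, TRUE),
    st("P2", FALSE, FALSE),
    st("P3", FALSE, FALSE),
    st("P4", FALSE, FALSE),
    st("P5", FALSE, FALSE),
    st("P6", FALSE, FALSE),
    st("P7", FALSE, FALSE))

  tr <- function(from, to, rate, kind)
    data.frame(from = from, to = to, rate = rate, kind = kind,
               stringsAsFactors = FALSE)
  kbG_c <- elong$kb_G * conc_EFG
  trans <- rbind(
    tr("C0", "H0", k01, "conformational"),
    tr("H0", "H2", kbG_c, "binding"),
    tr("H2E", "POST", elong$k4, "conformational"),
    tr("POST", "P1", elong$k6, "conformational"),
    tr("P1", "P2", elong$k7, "dissociation"),
    tr("P2", "P3", kb_TC_nr * conc_TC_next, "binding"),
    tr("P3", "P4", k_codon, "conformational"),
    tr("P4", "P5", k_codon, "chemistry"),
    tr("P5", "P6", k_codon, "conformational"),
    tr("P6", "P7", k_codon, "conformational"),
    tr("P7", "C0", k_codon, "chemistry"))

  branch_targets <- c("H2E")
  branch_probs <- c(branch$p_e1)

  if (site_type != "single_stranded") {
    states <- rbind(states,
                    st("FC", FALSE, TRUE),
                    st("FH", TRUE, TRUE),
                    st("FH1", TRUE, FALSE))
    trans <- rbind(trans,
                   tr("FC", "FH", elong$k14, "conformational"),
                   tr("FH", "FH1", elong$kr, "dissociation"),
                   tr("FH1", "H2", kbG_c, "binding"))
    branch_targets <- c(branch_targets, "FC")
    branch_probs <- c(branch_probs, branch$p_f1)
  }

  rates_eff <- NULL
  if (site_type == "duplex_slippery") {
    stopifnot(inherits(sampling, "sampling_rates"))
    .check_positive(conc_TC, "conc_TC")
    kb1G_c <- arrival$kb1_G * conc_EFG
    kb1TC_c <- arrival$kb1_TC * conc_TC
    rates_eff <- sampling
    rates_eff$k24 <- kb1G_c
    rates_eff$k26 <- kb1G_c
    states <- rbind(states,
                    st("LP", FALSE, TRUE),
                    st("FS", TRUE, TRUE),
                    st("FSb", TRUE, TRUE),
                    st("FS1", TRUE, FALSE),
                    st("FSG", TRUE, TRUE),
                    st("FS2", TRUE, FALSE, "sampling"),
                    st("FS3", TRUE, FALSE, "sampling"),
                    st("FS4", TRUE, FALSE, "accommodated"),
                    st("FS5", TRUE, FALSE),
                    st("FS6", TRUE, TRUE),
                    st("FS7", FALSE, TRUE),
                    st("FS7b", FALSE, TRUE),
                    st("FS8", TRUE, TRUE, "accommodated"),
                    st("FS9", TRUE, TRUE, "accommodated"),
                    st("FS10", FALSE, TRUE),
                    st("F10b", FALSE, TRUE),
                    st("F10c", FALSE, FALSE))
    fs3_entry <- "FS3"
    if (p_frame0 > 0) {
      states <- rbind(states,
                      st("FSR", TRUE, FALSE, "sampling"),
                      st("RECm1", TRUE, FALSE, "sampling"),
                      st("REC0", TRUE, FALSE, "sampling"))
      fs3_entry <- "FSR"
    }
    trans <- rbind(trans,
                   tr("LP", "FS", k16, "conformational"),
                   tr("FS", "FSb", elong$k6, "conformational"),
                   tr("FSb", "FS1", elong$k7, "dissociation"),
                   tr("FS1", "FSG", kb1G_c, "binding"),
                   tr("FSG", "FS1", 1 / arrival$T_G, "dissociation"),
                   tr("FS1", "FS2", kb1TC_c, "binding"),
                   tr("FS2", fs3_entry, sampling$k20, "conformational"),
                   tr("FS2", "FS1", sampling$k21, "dissociation"),
                   tr("FS3", "FS4", sampling$k22, "conformational"),
                   tr("FS3", "FS5", sampling$k23, "dissociation"),
                   tr("FS5", "FS6", kb1G_c, "binding"),
                   tr("FS6", "FS7", sampling$k25, "conformational"),
                   tr("FS7", "FS7b", elong$k6, "conformational"),
                   tr("FS7b", "P2", elong$k7, "dissociation"),
                   tr("FS4", "FS8", kb1G_c, "binding"),
                   tr("FS8", "FS9", sampling$k27, "conformational"),
                   tr("FS9", "FS10", sampling$k28, "conformational"),
                   tr("FS10", "F10b", elong$k6, "conformational"),
                   tr("F10b", "F10c", elong$k7, "dissociation"),
                   tr("F10c", "C0", k_codon, "chemistry"))
    branch_targets <- c(branch_targets, "LP")
    branch_probs <- c(branch_probs, branch$p_lp1)
  }

  branches <- list(H2 = list(targets = branch_targets,
                             probs = branch_probs / sum(branch_probs)))
  if (site_type == "duplex_slippery" && p_frame0 > 0) {
    branches$FSR <- list(targets = c("RECm1", "REC0"),
                         probs = c(1 - p_frame0, p_frame0))
    # the frame markers themselves resolve instantaneously onto the
    # shared recognition state
    branches$RECm1 <- list(targets = "FS3", probs = 1)
    branches$REC0 <- list(targets = "FS3", probs = 1)
  }

  if (branch_mode == "rates") {
    for (bs in names(branches)) {
      b <- branches[[bs]]
      keep <- b$probs > 0
      trans <- rbind(trans,
                     tr(bs, b$targets[keep], branch_rate * b$probs[keep],
                        "branch"))
    }
    branches <- list()
  } else {
    for (bs in names(branches)) {
      b <- branches[[bs]]
      keep <- b$probs > 0
      branches[[bs]]$targets <- b$targets[keep]
      branches[[bs]]$probs <- b$probs[keep]
    }
  }

  bad <- !(trans$rate > 0) | !is.finite(trans$rate)
  if (any(bad))
    stop("configuration error: non-positive or non-finite rate on ",
         paste(sprintf("%s -> %s", trans$from[bad], trans$to[bad]),
               collapse = ", "), call. = FALSE)
  miss <- setdiff(c(trans$from, trans$to,
                    unlist(lapply(branches, `[[`, "targets"))),
                  states$name)
  if (length(miss))
    stop("configuration error: undeclared state ",
         paste(miss, collapse = ", "), call. = FALSE)

  structure(
    list(site_type = site_type, states = states, transitions = trans,
         branches = branches, initial = "C0", branch = branch,
         params = list(elong = elong, sampling = sampling,
                       sampling_effective = rates_eff, arrival = arrival,
                       conc_EFG = conc_EFG, conc_TC = conc_TC,
                       conc_TC_next = conc_TC_next, kb_TC_nr = kb_TC_nr,
                       k01 = k01, k16 = k16,
                       k_codon = k_codon, p_frame0 = p_frame0,
                       branch_mode = branch_mode)),
    class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat(sprintf("Elongation state network (%s): %d states, %d transitions\n",
              x$site_type, nrow(x$states), nrow(x$transitions)))
  b <- x$branch
  cat(sprintf("  branch at unlocked state: P_E(1) = %.3f  P_F(1) = %.3f  P_LP(1) = %.3f\n",
              b$p_e1, b$p_f1, b$p_lp1))
  cat(sprintf("  [EF-G] = %g uM, [TC] = %g uM (sampled codon), %g uM (next codon)\n",
              x$params$conc_EFG, x$params$conc_TC, x$params$conc_TC_next))
  invisible(x)
}

#' Simulate elongation cycles over a state network
#'
#' Runs the exact stochastic simulation algorithm over the declared
#' network for `n_cycles` elongation cycles (walks from the initial
#' state back to itself), returning the full event list.  Runs with the
#' same seed are identical.
#'
#' @param network a [build_network()] object.
#' @param n_cycles number of elongation cycles (>= 1).
#' @param seed integer RNG seed.
#' @param max_events event budget guarding against runaway simulations.
#' @return An object of class `"ctmc_sim"`: a list with `events` (a
#'   data.frame with columns `cycle`, `time`, `from`, `to`; times are
#'   cumulative across the run), the `network`, `n_cycles` and `seed`.
#' @examples
#' net <- build_network("single_stranded")
#' sim <- simulate_network(net, n_cycles = 100, seed = 1)
#' head(sim$events)
#' @export
simulate_network <- function(network, n_cycles, seed,
                             max_events = max(1e6, 500 * n_cycles)) {
  stopifnot(inherits(network, "state_network"))
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1)
    stop("'n_cycles' must be >= 1", call. = FALSE)
  n_cycles <- as.integer(n_cycles)

  nm <- network$states$name
  idx <- stats::setNames(seq_along(nm), nm)
  is_branch <- logical(length(nm))
  from_i <- idx[network$transitions$from]
  to_i <- idx[network$transitions$to]
  rate <- network$transitions$rate
  for (bs in names(network$branches)) {
    b <- network$branches[[bs]]
    is_branch[idx[[bs]]] <- TRUE
    from_i <- c(from_i, rep(idx[[bs]], length(b$targets)))
    to_i <- c(to_i, idx[b$targets])
    rate <- c(rate, b$probs)
  }
  ord <- order(from_i)
  from_i <- from_i[ord]; to_i <- to_i[ord]; rate <- rate[ord]
  offset <- c(0L, cumsum(tabulate(from_i, nbins = length(nm))))
  rate_sum <- as.vector(rowsum(rate, from_i,
                               reorder = TRUE))
  rs <- numeric(length(nm))
  rs[sort(unique(from_i))] <- rate_sum
  # states with no outgoing transitions are caught in C++ if reached

  set.seed(as.integer(seed))
  res <- .gillespie_cpp(length(nm), idx[[network$initial]] - 1L, n_cycles,
                        as.integer(offset), as.integer(to_i - 1L),
                        as.numeric(rate), is_branch, rs,
                        as.numeric(max_events))
  events <- data.frame(cycle = res$cycle, time = res$time,
                       from = nm[res$from], to = nm[res$to],
                       stringsAsFactors = FALSE)
  structure(list(events = events, network = network, n_cycles = n_cycles,
                 seed = as.integer(seed)),
            class = "ctmc_sim")
}

#' @export
print.ctmc_sim <- function(x, ...) {
  cat(sprintf("Stochastic simulation: %d cycles, %d events, seed %d (%s)\n",
              x$n_cycles, nrow(x$events), x$seed, x$network$site_type))
  invisible(x)
}
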