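# Synthetic single-molecule trace generation.
#
# Presets bundle the construct energetics and the kinetic defaults into
# ready-to-simulate networks at the working concentrations of the
# single-molecule experiments ([EF-G] = 80 nM, sampled-codon ternary
# complex 200 nM, next-codon ternary complex 1 uM unless overridden).

#' Construct energetics of the dnaX frameshift messages
#'
#' Energy parameters of the wild-type message and the two signal-deletion
#' mutants, using the fitted free energies `delta_E = 3`,
#' `delta_delta_ESD = 1.6`, `E_bp = 2.5` (kBT).
#'
#' @param construct `"wt"`, `"no_sd"` (internal SD deleted) or
#'   `"no_hairpin"` (downstream hairpin deleted).
#' @param branch_mass target single-rotation probability mass
#'   `p_e1 + p_lp1` used to pin the futile-branch barrier `E_PE50S`;
#'   defaults to 0.57 for the wild type and 0.8 for the less obstructed
#'   mutants.
#' @return An [energy_params()] object with `E_PE50S` set.
#' @export
dnax_energies <- function(construct = c("wt", "no_sd", "no_hairpin"),
                          branch_mass = NULL) {
  construct <- match.arg(construct)
  en <- switch(construct,
    wt = energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 1.6,
                       E_bp = 2.5),
    no_sd = energy_params(delta_E = 3, delta_ESD2 = 0, delta_ESD3 = 0,
                          E_bp = 2.5),
    no_hairpin = energy_params(delta_E = 3, delta_ESD2 = 0,
                               delta_ESD3 = 1.6, E_bp = 0))
  if (is.null(branch_mass))
    branch_mass <- if (construct == "wt") 0.57 else 0.8
  en$E_PE50S <- e_pe50s_for_branch_mass(en, branch_mass)
  energy_params(delta_E = en$delta_E, delta_ESD2 = en$delta_ESD2,
                delta_ESD3 = en$delta_ESD3, E_bp = en$E_bp,
                E_PE50S = en$E_PE50S)
}

.TRACE_PRESETS <- c("fig1_single_stranded", "fig2_duplex",
                    "fig3_wt_slippery", "fig3_no_sd", "fig3_no_hairpin",
                    "force_sweep")

#' Preset elongation networks
#'
#' Builds the state network for one of the named study conditions:
#' translation of a single-stranded message, of a duplex non-slippery
#' codon under the SD-antiSD interaction (effective-translocation
#' probability 0.25), of the slippery codon of the wild-type or
#' signal-deletion messages, or of a hairpin-free SD-free slippery
#' message under an external force (`delta_E = 3.5` kBT).
#'
#' @param preset one of `"fig1_single_stranded"`, `"fig2_duplex"`,
#'   `"fig3_wt_slippery"`, `"fig3_no_sd"`, `"fig3_no_hairpin"`,
#'   `"force_sweep"`.
#' @param conc_EFG,conc_TC,conc_TC_next working concentrations (uM).
#' @param force a [force_context()] for `"force_sweep"`.
#' @param delta_E_force codon/tRNA energy (kBT) of the force preset.
#' @param E_PE50S_force futile barrier (kBT) of the force preset; the
#'   observed branching constrains only the non-futile channels, so this
#'   reuses the wild-type pinned value by default.
#' @param ... further arguments passed to [build_network()].
#' @return A `"state_network"`.
#' @export
network_preset <- function(preset = .TRACE_PRESETS, conc_EFG = 0.08,
                           conc_TC = 0.2, conc_TC_next = 1,
                           force = force_context(),
                           delta_E_force = 3.5, E_PE50S_force = NULL,
                           ...) {
  preset <- match.arg(preset)
  if (preset == "fig1_single_stranded")
    return(build_network("single_stranded", conc_EFG = conc_EFG,
                         conc_TC = conc_TC, conc_TC_next = conc_TC_next,
                         ...))
  if (preset == "fig2_duplex") {
    br <- branch_probs(p_lp1 = 0, p_e1 = 0.25)
    return(build_network("duplex_nonslippery", branch = br,
                         conc_EFG = conc_EFG, conc_TC = conc_TC,
                         conc_TC_next = conc_TC_next, ...))
  }
  if (preset == "force_sweep") {
    if (is.null(E_PE50S_force))
      E_PE50S_force <- dnax_energies("wt")$E_PE50S
    br <- branch_probabilities_force(delta_E_force, E_PE50S_force, force)
    return(build_network("duplex_slippery", branch = br,
                         conc_EFG = conc_EFG, conc_TC = conc_TC,
                         conc_TC_next = conc_TC_next, ...))
  }
  construct <- switch(preset, fig3_wt_slippery = "wt",
                      fig3_no_sd = "no_sd", fig3_no_hairpin = "no_hairpin")
  br <- branch_probabilities(dnax_energies(construct))
  build_network("duplex_slippery", branch = br, conc_EFG = conc_EFG,
                conc_TC = conc_TC, conc_TC_next = conc_TC_next, ...)
}

#' Generate synthetic single-molecule traces
#'
#' Simulates `n_molecules` molecules, each translating the focal codon
#' once, and returns their event tables in a per-molecule clock.  The
#' statistical structure of the traces (dwell distributions, pulse
#' counts, branch fractions) is exactly that of the declared network.
#'
#' @param preset a [network_preset()] name.
#' @param n_molecules number of molecules (0 gives an empty table).
#' @param seed integer RNG seed.
#' @param ... passed to [network_preset()].
#' @return An object of class `"trace_set"`: a list with `events` (a
#'   data.frame with `molecule_id`, `time_s`, `source_state`,
#'   `target_state`), the `preset`, `seed`, `network` and the underlying
#'   `"ctmc_sim"` (`sim`, `NULL` when `n_molecules = 0`).
#' @examples
#' tr <- generate_synthetic_traces("fig3_wt_slippery", 50, seed = 1)
#' head(tr$events)
#' @export
generate_synthetic_traces <- function(preset, n_molecules, seed, ...) {
  preset <- match.arg(preset, .TRACE_PRESETS)
  net <- network_preset(preset, ...)
  if (n_molecules == 0) {
    ev <- data.frame(molecule_id = integer(), time_s = numeric(),
                     source_state = character(),
                     target_state = character(),
                     stringsAsFactors = FALSE)
    return(structure(list(events = ev, preset = preset,
                          seed = as.integer(seed), network = net,
                          sim = NULL),
                     class = "trace_set"))
  }
  sim <- simulate_network(net, n_cycles = n_molecules, seed = seed)
  ev <- sim$events
  ## per-molecule clock: measure from the end of the previous molecule
  prev_end <- c(0, ev$time[cumsum(rle(ev$cycle)$lengths)])
  offs <- prev_end[ev$cycle]
  out <- data.frame(molecule_id = ev$cycle, time_s = ev$time - offs,
                    source_state = ev$from, target_state = ev$to,
                    stringsAsFactors = FALSE)
  structure(list(events = out, preset = preset, seed = as.integer(seed),
                 network = net, sim = sim),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Synthetic traces: preset %s, %d molecules, seed %d\n",
              x$preset, length(unique(x$events$molecule_id)), x$seed))
  invisible(x)
}

#' Write synthetic traces as a tab-separated event table
#'
#' Writes `molecule_id`, `time_s`, `source_state`, `target_state` as TSV
#' with a comment header recording the preset and seed for provenance.
#'
#' @param traces a `"trace_set"` from [generate_synthetic_traces()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_events <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# preset: %s", traces$preset), con)
  writeLines(sprintf("# seed: %d", traces$seed), con)
  utils::write.table(traces$events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
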