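# Trajectory summaries: the observables of the single-molecule
# experiments, estimated from simulated event lists.
#
# Every mean carries its Monte-Carlo standard error so closed-form
# predictions can be tested at a stated number of standard errors.

.mean_se <- function(x) {
  n <- length(x)
  if (n == 0L) return(c(mean = NA_real_, se = NA_real_, n = 0))
  c(mean = mean(x), se = stats::sd(x) / sqrt(n), n = n)
}

#' Summarize simulated trajectories into the model's observables
#'
#' Reduces a [simulate_network()] event list to the per-cycle and
#' per-event statistics the closed-form theory predicts:
#'
#' * `p_lp_hat` - fraction of cycles entering the long-paused state;
#' * `frameshift_fraction` - fraction of cycles committing to the -1
#'   frame (equal to `p_lp_hat` when no 0-frame-restoring tRNA competes
#'   in the long pause);
#' * `n_samplings_hat` - mean number of tRNA samplings per long pause;
#' * `t_trna_hat` - mean duration of a tRNA binding pulse (contiguous
#'   occupancy of the sampled/accommodated tRNA states);
#' * `tau_hat` - mean waiting time from the opening of the long-paused
#'   state to the next productive ternary-complex arrival, EF-G visits
#'   included;
#' * `n_efg_hat`, `t_efg_hat` - EF-G bindings per cycle and mean bound
#'   lifetime, split into `canonical` bindings (to the pre-translocation
#'   rotated state, futile rounds included), `lp` bindings (to the open
#'   long-paused rotated state) and `resolving` bindings (the final
#'   EF-G.GTP arrivals that resolve the pause), with `n_efg_hat`
#'   counting canonical plus long-pause bindings;
#' * `t_rot_hat`, `t_rot_lp_hat`, `t_rot_nl_hat` - mean rotated-state
#'   dwell per cycle (total time in rotated-flagged states; non-rotated
#'   interruptions shorter than `resolution` are invisible, as in the
#'   FRET recordings, and interruptions are counted in
#'   `n_interruptions_resolved` when they exceed it), overall and
#'   conditioned on entering / avoiding the long pause;
#' * `t_nr_hat` - mean non-rotated time per cycle.
#'
#' @param sim a `"ctmc_sim"` object from [simulate_network()].
#' @param resolution shortest non-rotated interruption (s) the assumed
#'   recording could resolve; default 0.1 s.
#' @return An object of class `"trace_summary"`: a list of named
#'   `c(mean, se, n)` vectors plus bookkeeping fields.
#' @export
summarize_trajectories <- function(sim, resolution = 0.1) {
  stopifnot(inherits(sim, "ctmc_sim"))
  ev <- sim$events
  if (nrow(ev) == 0L) stop("empty trajectory list", call. = FALSE)
  net <- sim$network
  states <- net$states
  sidx <- stats::setNames(seq_len(nrow(states)), states$name)
  from_i <- sidx[ev$from]
  cyc <- ev$cycle
  n_cycles <- sim$n_cycles
  dur <- diff(c(0, ev$time))

  res <- list(n_cycles = n_cycles, resolution = resolution,
              site_type = net$site_type)

  ## -- long-pause entry and frame bookkeeping ------------------------
  has_lp <- "LP" %in% states$name
  lp_cycle <- rep(FALSE, n_cycles)
  if (has_lp) lp_cycle[unique(cyc[ev$to == "LP"])] <- TRUE
  p <- mean(lp_cycle)
  res$p_lp_hat <- c(mean = p, se = sqrt(p * (1 - p) / n_cycles),
                    n = n_cycles)

  fs_cycle <- lp_cycle
  if (has_lp && net$params$p_frame0 > 0) {
    rec <- which(ev$from == "FSR")
    if (length(rec)) {
      last <- tapply(rec, cyc[rec], max)
      kept0 <- as.integer(names(last))[ev$to[last] == "REC0"]
      fs_cycle[kept0] <- FALSE
    }
  }
  pf <- mean(fs_cycle)
  res$frameshift_fraction <- c(mean = pf,
                               se = sqrt(pf * (1 - pf) / n_cycles),
                               n = n_cycles)

  ## -- tRNA sampling statistics --------------------------------------
  if (has_lp && any(lp_cycle)) {
    ns <- tabulate(cyc[ev$to == "FS2"], nbins = n_cycles)[lp_cycle]
    res$n_samplings_hat <- .mean_se(ns)

    bound <- states$trna[from_i] != "none"
    key <- cyc * 2L + as.integer(bound)
    r <- rle(key)
    runid <- rep.int(seq_along(r$lengths), r$lengths)
    run_dur <- as.vector(rowsum(dur, runid, reorder = TRUE))
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    run_bound <- bound[run_start]
    res$t_trna_hat <- .mean_se(run_dur[run_bound])

    ## ternary-complex arrival times: from each (re)opening of FS1
    ## (entry not from the EF-G-bound excursion) to the next FS2 entry
    open_idx <- which(ev$to == "FS1" & ev$from != "FSG")
    arr_idx <- which(ev$to == "FS2")
    if (length(arr_idx) && length(open_idx)) {
      j <- findInterval(arr_idx, open_idx)
      ok <- j >= 1L
      res$tau_hat <- .mean_se(ev$time[arr_idx[ok]] -
                                ev$time[open_idx[j[ok]]])
    }
  }

  ## -- EF-G binding statistics ---------------------------------------
  efg <- states$efg[from_i]
  key <- cyc * 2L + as.integer(efg)
  r <- rle(key)
  runid <- rep.int(seq_along(r$lengths), r$lengths)
  run_dur <- as.vector(rowsum(dur, runid, reorder = TRUE))
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_efg <- efg[run_start]
  run_cyc <- cyc[run_start]
  is_lp_visit <- as.vector(rowsum(as.numeric(ev$from == "FSG"), runid,
                                  reorder = TRUE)) > 0
  is_resolving <- as.vector(
    rowsum(as.numeric(ev$from %in% c("FS6", "FS8")), runid,
           reorder = TRUE)) > 0
  cls <- ifelse(is_lp_visit, "lp",
                ifelse(is_resolving, "resolving", "canonical"))
  keep <- run_efg
  res$t_efg_canonical_hat <- .mean_se(run_dur[keep & cls == "canonical"])
  res$t_efg_lp_hat <- .mean_se(run_dur[keep & cls == "lp"])
  res$t_efg_resolving_hat <- .mean_se(run_dur[keep & cls == "resolving"])
  res$t_efg_hat <- .mean_se(run_dur[keep & cls != "resolving"])

  cnt <- function(which_runs)
    tabulate(run_cyc[which_runs], nbins = n_cycles)
  n_can <- cnt(keep & cls == "canonical")
  n_lp <- cnt(keep & cls == "lp")
  res$n_efg_canonical_hat <- .mean_se(n_can)
  if (has_lp && any(lp_cycle)) res$n_efg_lp_hat <- .mean_se(n_lp[lp_cycle])
  res$n_efg_hat <- .mean_se(n_can + n_lp)

  ## -- rotated-state dwells ------------------------------------------
  rot <- states$rotated[from_i]
  key <- cyc * 2L + as.integer(rot)
  r <- rle(key)
  runid <- rep.int(seq_along(r$lengths), r$lengths)
  run_dur <- as.vector(rowsum(dur, runid, reorder = TRUE))
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_rot <- rot[run_start]
  run_cyc <- cyc[run_start]
  rot_tot <- as.vector(rowsum(run_dur[run_rot], run_cyc[run_rot],
                              reorder = TRUE))
  rot_cycles <- sort(unique(run_cyc[run_rot]))
  per_cycle_rot <- numeric(n_cycles)
  per_cycle_rot[rot_cycles] <- rot_tot
  res$t_rot_hat <- .mean_se(per_cycle_rot)
  if (has_lp && any(lp_cycle) && any(!lp_cycle)) {
    res$t_rot_lp_hat <- .mean_se(per_cycle_rot[lp_cycle])
    res$t_rot_nl_hat <- .mean_se(per_cycle_rot[!lp_cycle])
  }
  ## interruptions a recording at `resolution` would have resolved:
  ## interior non-rotated runs (bounded by rotated runs of the same
  ## cycle) longer than the resolution
  nr <- which(!run_rot)
  interior <- nr[nr > 1L & nr < length(run_rot)]
  interior <- interior[run_rot[interior - 1L] & run_rot[interior + 1L] &
                         run_cyc[interior - 1L] == run_cyc[interior] &
                         run_cyc[interior + 1L] == run_cyc[interior]]
  res$n_interruptions_resolved <- sum(run_dur[interior] > resolution)

  nr_tot <- as.vector(rowsum(run_dur[!run_rot], run_cyc[!run_rot],
                             reorder = TRUE))
  nr_cycles <- sort(unique(run_cyc[!run_rot]))
  per_cycle_nr <- numeric(n_cycles)
  per_cycle_nr[nr_cycles] <- nr_tot
  res$t_nr_hat <- .mean_se(per_cycle_nr)

  structure(res, class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("Trace summary (%s, %d cycles):\n", x$site_type,
              x$n_cycles))
  flds <- setdiff(names(x), c("n_cycles", "resolution", "site_type",
                              "n_interruptions_resolved"))
  for (f in flds) {
    v <- x[[f]]
    if (is.numeric(v) && length(v) == 3L)
      cat(sprintf("  %-22s %10.4g +/- %.3g  (n = %d)\n", f, v[["mean"]],
                  v[["se"]], as.integer(v[["n"]])))
  }
  invisible(x)
}
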