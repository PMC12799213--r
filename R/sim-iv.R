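#' Boltzmann-gated ohmic current
#'
#' Closed form `I(V) = g_max (V - v_rev) / (1 + exp(-(V - vhalf)/k))`, the
#' standard activation model for L-type CaV current-voltage relations.
#'
#' @param v membrane voltage, mV (after junction-potential correction).
#' @param vhalf half-activation voltage, mV.
#' @param slope_k slope factor, mV (nonzero).
#' @param g_max maximal conductance, nS.
#' @param v_rev reversal potential, mV.
#' @return current in pA.
#' @export
boltzmann_current <- function(v, vhalf, slope_k, g_max, v_rev) {
  if (any(slope_k == 0)) abort("`slope_k` must be nonzero")
  g_max * (v - v_rev) / (1 + exp(-(v - vhalf) / slope_k))
}

#' Standard step-depolarization protocol
#'
#' Command voltages from -65 to +80 mV in 5 mV steps; after offline
#' correction of a 21.2 mV liquid junction potential these span
#' -86.2 to +58.8 mV (30 sweeps).
#'
#' @param from,to,by command voltages, mV.
#' @return numeric vector of command voltages.
#' @export
iv_protocol <- function(from = -65, to = 80, by = 5) seq(from, to, by = by)

#' Generate a whole-cell voltage-clamp recording
#'
#' Sweep currents follow a Boltzmann-gated ohmic model plus an ohmic leak
#' (reversal 0 mV) and Gaussian noise. Membrane voltage during each step is
#' the command voltage minus the liquid junction potential. Optionally p/10
#' leak sweeps (1/10-amplitude replicas of each test pulse, passing only
#' leak current) are attached for leak subtraction.
#'
#' @param vhalf,slope_k,g_max,v_rev activation parameters
#'   (see [boltzmann_current()]).
#' @param leak_conductance ohmic leak, nS.
#' @param capacitance membrane capacitance, pF.
#' @param rs series resistance, MOhm (metadata for QC).
#' @param noise_sd per-sample current noise SD, pA.
#' @param protocol strictly increasing command voltages, mV.
#' @param ljp liquid junction potential, mV (21.2 or 18 in practice).
#' @param holding_cmd holding command voltage, mV.
#' @param step_ms,pre_ms,post_ms,dt_ms timing of each sweep, ms.
#' @param offset_drift recorded offset-potential drift, mV (QC metadata).
#' @param include_p10 attach p/10 leak sweeps.
#' @param seed RNG seed.
#' @return object of class `iv_recording`.
#' @export
generate_iv_recording <- function(vhalf = -15, slope_k = 8, g_max = 2,
                                  v_rev = 60, leak_conductance = 0.2,
                                  capacitance = 15, rs = 8, noise_sd = 2,
                                  protocol = iv_protocol(), ljp = 21.2,
                                  holding_cmd = -70, step_ms = 20,
                                  pre_ms = 5, post_ms = 5, dt_ms = 0.1,
                                  offset_drift = 0, include_p10 = TRUE,
                                  seed = 1L) {
  if (any(diff(protocol) <= 0)) abort("protocol voltages must be strictly increasing")
  if (slope_k == 0) abort("`slope_k` must be nonzero")
  time_ms <- seq(0, pre_ms + step_ms + post_ms - dt_ms, by = dt_ms)
  in_step <- time_ms >= pre_ms & time_ms < pre_ms + step_ms
  nt <- length(time_ms); ns <- length(protocol)
  vh <- holding_cmd - ljp
  leak <- function(v) leak_conductance * v  # leak reversal at 0 mV

  sweeps <- matrix(0, nt, ns)
  leak_sweeps <- if (include_p10) matrix(0, nt, ns) else NULL
  for (s in seq_len(ns)) {
    vm <- protocol[s] - ljp
    tr <- leak(vh) + numeric(nt)
    tr[in_step] <- leak(vm) + boltzmann_current(vm, vhalf, slope_k, g_max, v_rev)
    sweeps[, s] <- tr
    if (include_p10) {
      vm10 <- vh + (vm - vh) / 10
      lt <- leak(vh) + numeric(nt)
      lt[in_step] <- leak(vm10)
      leak_sweeps[, s] <- lt
    }
  }
  if (noise_sd > 0) {
    sweeps <- with_seed(seed, sweeps + rnorm(length(sweeps), 0, noise_sd))
    if (include_p10)
      leak_sweeps <- with_seed(seed + 1L,
                               leak_sweeps + rnorm(length(leak_sweeps), 0, noise_sd))
  }
  structure(list(time_ms = time_ms, sweeps = sweeps, leak_sweeps = leak_sweeps,
                 command_mV = protocol, holding_cmd = holding_cmd, ljp = ljp,
                 ljp_corrected = FALSE, onset_ms = pre_ms, step_ms = step_ms,
                 capacitance = capacitance, rs = rs,
                 leak_at_holding = leak(vh), offset_drift = offset_drift,
                 truth = list(vhalf = vhalf, slope_k = slope_k, g_max = g_max,
                              v_rev = v_rev, leak_conductance = leak_conductance,
                              noise_sd = noise_sd)),
            class = "iv_recording")
}

#' @export
print.iv_recording <- function(x, ...) {
  cat(sprintf("<iv_recording> %d sweeps (%.1f..%.1f mV cmd), %d samples/sweep\n",
              length(x$command_mV), min(x$command_mV), max(x$command_mV),
              length(x$time_ms)))
  cat(sprintf("  Cm=%g pF, Rs=%g MOhm, LJP=%g mV (%scorrected), leak@holding=%.1f pA\n",
              x$capacitance, x$rs, x$ljp, if (x$ljp_corrected) "" else "not ",
              x$leak_at_holding))
  invisible(x)
}
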