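#' Correct command voltages for the liquid junction potential
#'
#' Subtracts the recording's LJP (21.2 or 18 mV depending on the internal
#' solution) from every command voltage; applied once, offline.
#'
#' @param recording an `iv_recording`.
#' @return the recording with corrected voltages and `ljp_corrected = TRUE`.
#' @export
correct_ljp <- function(recording) {
  stopifnot(inherits(recording, "iv_recording"))
  if (recording$ljp_corrected) {
    warn("voltages already LJP-corrected; returning unchanged")
    return(recording)
  }
  recording$command_mV <- recording$command_mV - recording$ljp
  recording$holding_cmd <- recording$holding_cmd - recording$ljp
  recording$ljp_corrected <- TRUE
  recording
}

#' p/10 leak subtraction
#'
#' Subtracts ten times the baseline-referenced response to 1/10-amplitude
#' leak pulses from the baseline-referenced test sweeps. For a purely ohmic
#' (leak-only) cell the corrected currents are identically zero up to
#' noise.
#'
#' @param recording an `iv_recording` carrying `leak_sweeps`, or a numeric
#'   matrix of test sweeps (then `leak_sweeps` must be given).
#' @param leak_sweeps matrix matching the test sweeps (when `recording` is
#'   a matrix).
#' @param baseline_idx sample indices of the pre-pulse baseline; defaults
#'   to all samples before step onset.
#' @return the recording (or matrix) with leak-corrected sweeps.
#' @export
leak_correct_p10 <- function(recording, leak_sweeps = NULL, baseline_idx = NULL) {
  if (is.matrix(recording)) {
    if (is.null(leak_sweeps)) abort("leak sweeps are missing")
    test <- recording
    if (is.null(baseline_idx)) baseline_idx <- seq_len(max(1L, nrow(test) %/% 6L))
    corr <- p10_subtract(test, leak_sweeps, baseline_idx)
    return(corr)
  }
  stopifnot(inherits(recording, "iv_recording"))
  if (is.null(recording$leak_sweeps)) abort("leak sweeps are missing")
  if (is.null(baseline_idx))
    baseline_idx <- which(recording$time_ms < recording$onset_ms)
  recording$sweeps <- p10_subtract(recording$sweeps, recording$leak_sweeps,
                                   baseline_idx)
  recording$leak_corrected <- TRUE
  recording
}

p10_subtract <- function(test, leak, baseline_idx) {
  tb <- colMeans(test[baseline_idx, , drop = FALSE])
  lb <- colMeans(leak[baseline_idx, , drop = FALSE])
  sweep_center <- function(m, b) sweep(m, 2L, b, "-")
  sweep_center(test, tb) - 10 * sweep_center(leak, lb)
}

#' Extract the IV relation
#'
#' Per sweep, averages the current over a window after step onset (default
#' 5-10 ms, capturing the early evoked Ca2+ current) and converts to
#' current density via the membrane capacitance.
#'
#' @param recording an `iv_recording` (LJP-correct it first so voltages are
#'   membrane potentials).
#' @param window `c(start, end)` in ms after step onset.
#' @return tibble of class `iv_curve` with `voltage` (mV), `current` (pA)
#'   and `density` (pA/pF); capacitance kept as attribute `capacitance`.
#' @export
extract_iv <- function(recording, window = c(5, 10)) {
  stopifnot(inherits(recording, "iv_recording"))
  t0 <- recording$onset_ms
  if (t0 + window[2] > max(recording$time_ms) + 1e-9)
    abort("extraction window extends beyond the sweep")
  idx <- which(recording$time_ms >= t0 + window[1] &
               recording$time_ms < t0 + window[2])
  if (!length(idx)) abort("extraction window contains no samples")
  cur <- colMeans(recording$sweeps[idx, , drop = FALSE])
  out <- tibble(voltage = recording$command_mV, current = cur,
                density = cur / recording$capacitance)
  class(out) <- c("iv_curve", class(out))
  attr(out, "capacitance") <- recording$capacitance
  out
}

#' Quality-control verdict for a recording
#'
#' Applies the exclusion rules: holding leak current above 50 pA in
#' magnitude, series resistance above 15 MOhm, offset-potential drift above
#' 5 mV, peak inward current below 49 pA in magnitude (too small), or peak
#' inward current density above 60 pA/pF in magnitude (too large).
#' Thresholds are compared strictly ("exceeded") and on magnitudes, with
#' inward currents negative.
#'
#' @param recording an `iv_recording`.
#' @param iv an [extract_iv()] result (leak-corrected recommended).
#' @param max_leak,max_rs,max_offset_drift,min_peak_current,max_peak_density
#'   the rule thresholds.
#' @return one-row tibble with `pass` and list-column `reasons`.
#' @export
qc_filter <- function(recording, iv, max_leak = 50, max_rs = 15,
                      max_offset_drift = 5, min_peak_current = 49,
                      max_peak_density = 60) {
  reasons <- character()
  if (abs(recording$leak_at_holding) > max_leak) reasons <- c(reasons, "leak_current")
  if (recording$rs > max_rs) reasons <- c(reasons, "series_resistance")
  if (abs(recording$offset_drift) > max_offset_drift) reasons <- c(reasons, "offset_drift")
  peak_inward <- min(iv$current)        # most negative = peak inward
  peak_density <- min(iv$density)
  if (abs(peak_inward) < min_peak_current) reasons <- c(reasons, "current_too_small")
  if (abs(peak_density) > max_peak_density) reasons <- c(reasons, "density_too_large")
  tibble(pass = length(reasons) == 0L, reasons = list(reasons))
}

#' Fit a Boltzmann-gated ohmic activation curve
#'
#' Least-squares fit of
#' `I(V) = g_max (V - V_rev) / (1 + exp(-(V - V_half)/k))`
#' to an IV relation, yielding the half-activation voltage and slope
#' factor.
#'
#' @param iv an [extract_iv()] result (needs >= 8 points spanning
#'   activation).
#' @return object of class `activation_fit`; non-convergence is flagged in
#'   `converged` with `NA` estimates. Use [generics::tidy()] /
#'   [generics::glance()] for tabular access.
#' @export
fit_activation <- function(iv) {
  if (nrow(iv) < 8) abort("need at least 8 IV points")
  df <- data.frame(v = iv$voltage, i = iv$current)
  if (sd(df$i) == 0) {
    # no voltage-dependent current: the activation curve is unidentifiable
    return(structure(list(estimates = c(vhalf = NA_real_, k = NA_real_,
                                        g_max = NA_real_, v_rev = NA_real_),
                          fit = NULL, converged = FALSE, data = df),
                     class = "activation_fit"))
  }
  i_min <- min(df$i)
  start <- list(vhalf = {
    cand <- df$v[df$i <= i_min / 2]
    if (length(cand)) min(cand) else median(df$v)
  }, k = 8, g_max = max(abs(i_min) / 60, 0.1), v_rev = {
    post <- df[df$v > df$v[which.min(df$i)], ]
    cross <- post$v[post$i >= 0]
    if (length(cross)) min(cross) else max(df$v) + 10
  })
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ g_max * (v - v_rev) / (1 + exp(-(v - vhalf) / k)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$convInfo$isConv
  est <- if (converged) coef(fit) else
    c(vhalf = NA_real_, k = NA_real_, g_max = NA_real_, v_rev = NA_real_)
  structure(list(estimates = est, fit = fit, converged = converged, data = df),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<activation_fit> did not converge\n")
  } else {
    e <- x$estimates
    cat(sprintf("<activation_fit> V_half=%.2f mV, k=%.2f mV, g_max=%.3f nS, V_rev=%.1f mV\n",
                e[["vhalf"]], e[["k"]], e[["g_max"]], e[["v_rev"]]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.activation_fit <- function(x, ...) {
  if (!x$converged)
    return(tibble(term = names(x$estimates), estimate = NA_real_,
                  std.error = NA_real_))
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @importFrom generics glance
#' @export
glance.activation_fit <- function(x, ...) {
  if (!x$converged)
    return(tibble(converged = FALSE, sigma = NA_real_, n = nrow(x$data)))
  tibble(converged = TRUE, sigma = summary(x$fit)$sigma, n = nrow(x$data))
}
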