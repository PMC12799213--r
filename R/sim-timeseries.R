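#' Single-plane fluorescence time series
#'
#' @param data numeric 3D array `[y, x, t]`.
#' @param pixel_size named `c(x, y)` pixel size, µm.
#' @param frame_rate acquisition rate, Hz.
#' @return object of class `time_series`.
#' @export
time_series <- function(data, pixel_size = c(x = 0.08, y = 0.08), frame_rate = 20) {
  if (length(dim(data)) != 3L) abort("`data` must be a [y, x, t] array")
  if (frame_rate <= 0) abort("`frame_rate` must be positive")
  structure(list(data = data, pixel_size = pixel_size[c("x", "y")],
                 frame_rate = frame_rate),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<time_series> %d x %d pixels, %d frames @ %g Hz\n",
              d[2], d[1], d[3], x$frame_rate))
  invisible(x)
}

#' Ground-truth table of stimulus-evoked transients
#'
#' Each row is a circular hotspot whose fluorescence follows
#' `F0 + amplitude * exp(-(t - onset)/decay_tau)` from stimulus onset
#' (a plateau when `decay_tau = Inf`); before onset the hotspot sits at its
#' baseline `F0`.
#'
#' @param x,y hotspot centre, µm.
#' @param F0 baseline fluorescence, a.u. (> 0).
#' @param amplitude evoked increase at onset, a.u. (>= 0).
#' @param onset_frame first stimulated frame (1-based).
#' @param duration_frames stimulus length in frames (500 ms at 20 Hz = 10).
#' @param decay_tau decay time constant, s (`Inf` = no decay).
#' @param radius hotspot radius, µm.
#' @return tibble with one row per transient.
#' @export
transient_table <- function(x, y, F0 = 100, amplitude = 50, onset_frame = 11,
                            duration_frames = 10, decay_tau = Inf, radius = 1) {
  tb <- tibble(roi_id = seq_along(x), x = x, y = y, F0 = F0,
               amplitude = amplitude, onset_frame = as.integer(onset_frame),
               duration_frames = as.integer(duration_frames),
               decay_tau = decay_tau, radius = radius)
  if (any(tb$F0 <= 0)) abort("F0 must be > 0")
  if (any(tb$amplitude < 0)) abort("amplitude must be >= 0")
  tb
}

# closed-form hotspot time course (length n_frames, a.u. above baseline)
transient_course <- function(amplitude, onset_frame, decay_tau, n_frames, frame_rate) {
  t_idx <- seq_len(n_frames)
  dt <- (t_idx - onset_frame) / frame_rate
  out <- numeric(n_frames)
  on <- t_idx >= onset_frame
  if (is.infinite(decay_tau)) out[on] <- amplitude
  else out[on] <- amplitude * exp(-dt[on] / decay_tau)
  out
}

#' Simulate a paired ROI study at the trace level
#'
#' Emulates the paired design of the stimulus-locked experiment: each cell
#' contributes one ROI at a ribbon-type site and one away from it, whose
#' true peak responses differ by a fixed ratio on top of log-normal
#' cell-to-cell and site-to-site variability; traces carry Gaussian noise
#' and are analysed with [dFmax_over_F0()].
#'
#' @param n_cells number of cells (the study's paired unit).
#' @param ratio true with/without peak-response ratio.
#' @param base_dfmax mean peak dF/F at sites without a ribbon.
#' @param site_sdlog log-SD of the per-site response variability.
#' @param f0 baseline fluorescence, a.u.
#' @param trace_noise_sd per-frame noise SD on the ROI-mean trace, a.u.
#' @param protocol a [stimulus_protocol()].
#' @param n_frames frames per trace.
#' @param frame_rate Hz.
#' @param decay_tau response decay constant, s.
#' @param seed RNG seed.
#' @return tibble with `cell_id`, `class`, `dfmax` suitable for
#'   [compare_roi_groups()].
#' @export
simulate_paired_roi_study <- function(n_cells = 24, ratio = 1.26,
                                      base_dfmax = 0.25, site_sdlog = 0.25,
                                      f0 = 100, trace_noise_sd = 1,
                                      protocol = stimulus_protocol(),
                                      n_frames = 25, frame_rate = 20,
                                      decay_tau = 1.5, seed = 1L) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(cell) {
      amp_without <- base_dfmax * rlnorm(1, 0, site_sdlog)
      amp_with <- base_dfmax * ratio * rlnorm(1, 0, site_sdlog)
      one <- function(amp, cls) {
        Ft <- f0 * (1 + transient_course(amp, protocol$onset_frame, decay_tau,
                                         n_frames, frame_rate)) +
          rnorm(n_frames, 0, trace_noise_sd)
        base_idx <- (protocol$onset_frame - protocol$pre_frames):(protocol$onset_frame - 1L)
        F0 <- mean(Ft[base_idx])
        tibble(cell_id = cell, class = cls,
               dfmax = dFmax_over_F0((Ft - F0) / F0, protocol)$value)
      }
      bind_rows(one(amp_with, "with_syribbon"),
                one(amp_without, "without_syribbon"))
    })
  })
}

#' Generate a stimulus-locked calcium-imaging time series
#'
#' Emulates single-plane spinning-disk imaging of a Ca2+ indicator during a
#' 500 ms depolarization: a uniform baseline, circular hotspots at punctum
#' sites following [transient_table()] kinetics, an optional diffuse
#' membrane-wide component (non-clustered channels), per-frame PSF blur and
#' Poisson + Gaussian noise.
#'
#' @param config a [sim_config()] (xy geometry and noise model are used).
#' @param transients a [transient_table()].
#' @param n_frames number of frames; must exceed every onset + duration.
#' @param frame_rate Hz.
#' @param baseline background fluorescence outside hotspots, a.u.
#' @param diffuse_amplitude amplitude of the membrane-ring component, a.u.
#' @param psf,noise stage toggles.
#' @return list with `series` (a [time_series]) and `truth`.
#' @export
generate_timeseries <- function(config, transients, n_frames = 40, frame_rate = 20,
                                baseline = 50, diffuse_amplitude = 0,
                                psf = TRUE, noise = TRUE) {
  if (frame_rate <= 0) abort("`frame_rate` must be positive")
  if (nrow(transients) &&
      any(n_frames <= transients$onset_frame + transients$duration_frames))
    abort("`n_frames` must exceed onset + duration for every transient")
  ny <- config$stack_shape[["y"]]; nx <- config$stack_shape[["x"]]
  ax <- voxel_axes(c(ny, nx, 1), config$voxel_size)
  base <- matrix(baseline, ny, nx)
  # hotspot masks and baselines
  masks <- vector("list", nrow(transients))
  for (k in seq_len(nrow(transients))) {
    dy <- outer((ax$y - transients$y[k])^2, (ax$x - transients$x[k])^2, "+")
    masks[[k]] <- dy <= transients$radius[k]^2
    base[masks[[k]]] <- transients$F0[k]
  }
  # diffuse membrane ring at the imaging plane (mid-plane ellipse)
  ring <- NULL
  if (diffuse_amplitude > 0) {
    u2 <- ((ax$x - config$cell_center[["x"]]) / config$cell_semiaxes[["x"]])^2
    v2 <- ((ax$y - config$cell_center[["y"]]) / config$cell_semiaxes[["y"]])^2
    rho <- sqrt(outer(v2, u2, "+"))
    w <- config$membrane_thickness / min(config$cell_semiaxes[c("x", "y")])
    ring <- rho <= 1 & rho >= 1 - w
  }
  courses <- lapply(seq_len(nrow(transients)), function(k)
    transient_course(transients$amplitude[k], transients$onset_frame[k],
                     transients$decay_tau[k], n_frames, frame_rate))
  ring_course <- if (!is.null(ring))
    transient_course(diffuse_amplitude, min(transients$onset_frame), Inf,
                     n_frames, frame_rate) else NULL

  sig_vox <- c(y = config$psf_sigma[["y"]] / config$voxel_size[["y"]],
               x = config$psf_sigma[["x"]] / config$voxel_size[["x"]])
  arr <- array(0, c(ny, nx, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- base
    for (k in seq_along(masks)) fr[masks[[k]]] <- fr[masks[[k]]] + courses[[k]][t]
    if (!is.null(ring)) fr[ring] <- fr[ring] + ring_course[t]
    if (psf && any(sig_vox > 0)) {
      fr3 <- array(fr, c(ny, nx, 1))
      fr <- smooth_gaussian(fr3, c(y = sig_vox[["y"]], x = sig_vox[["x"]], z = 0))[, , 1]
    }
    arr[, , t] <- fr
  }
  if (noise)
    arr <- with_seed(config$seed + 1L, {
      for (t in seq_len(n_frames)) arr[, , t] <- apply_noise(arr[, , t], config)
      arr
    })
  list(series = time_series(arr, config$voxel_size[c("x", "y")], frame_rate),
       truth = transients)
}
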