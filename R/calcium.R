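#' Stimulus protocol for stimulus-locked imaging
#'
#' Defaults describe a 500 ms depolarizing pulse imaged at 20 Hz: 10
#' stimulated frames, 5 baseline frames averaged for F0 and for the
#' delta-F image, and a 3-frame average at the in-window peak for
#' dFmax/F0.
#'
#' @param onset_frame first stimulated frame (1-based).
#' @param duration_frames stimulus length, frames.
#' @param pre_frames baseline frames immediately before onset.
#' @param stim_avg_frames frames averaged during stimulation.
#' @return a `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(onset_frame = 11L, duration_frames = 10L,
                              pre_frames = 5L, stim_avg_frames = 3L) {
  if (onset_frame <= pre_frames)
    abort("`onset_frame` must leave `pre_frames` baseline frames before it")
  if (duration_frames < stim_avg_frames)
    abort("`duration_frames` must be >= `stim_avg_frames`")
  structure(list(onset_frame = as.integer(onset_frame),
                 duration_frames = as.integer(duration_frames),
                 pre_frames = as.integer(pre_frames),
                 stim_avg_frames = as.integer(stim_avg_frames)),
            class = "stimulus_protocol")
}

#' Background subtraction for a time series
#'
#' Default method subtracts, per frame, the mean intensity of a designated
#' cell-free background region; results are clipped at zero. A per-frame
#' rolling-ball estimate is available as a fallback when no clean
#' background region exists.
#'
#' @param ts a [time_series].
#' @param bg_region logical matrix marking background pixels (ROI method).
#' @param method `"roi"` or `"rollingball"`.
#' @param ball_diameter rolling-ball diameter, µm (rolling-ball method).
#' @return the corrected [time_series].
#' @export
background_subtract_timeseries <- function(ts, bg_region = NULL,
                                           method = c("roi", "rollingball"),
                                           ball_diameter = 2) {
  stopifnot(inherits(ts, "time_series"))
  method <- match.arg(method)
  nT <- dim(ts$data)[3]
  if (method == "roi") {
    if (is.null(bg_region)) abort("`bg_region` is required for the ROI method")
    for (t in seq_len(nT)) {
      fr <- ts$data[, , t]
      ts$data[, , t] <- pmax(fr - mean(fr[bg_region]), 0)
    }
  } else {
    px <- ts$pixel_size[["x"]]
    diam_px <- max(round(ball_diameter / px), 1)
    if (diam_px %% 2 == 0) diam_px <- diam_px + 1
    brush <- EBImage::makeBrush(diam_px, shape = "disc")
    for (t in seq_len(nT)) {
      fr <- ts$data[, , t]
      mx <- max(fr, 1e-12)  # EBImage grayscale morphology works on [0, 1]
      ts$data[, , t] <- pmax(fr - EBImage::opening(fr / mx, brush) * mx, 0)
    }
  }
  ts
}

#' Pixelwise delta-F image
#'
#' Averages the `pre_frames` frames before stimulus onset and subtracts
#' them from the average of the first `stim_avg_frames` stimulated frames.
#' A 3 x 3 unweighted-smoothed copy is returned for display only; all
#' quantification uses the raw delta-F image.
#'
#' @param ts a (background-subtracted) [time_series].
#' @param protocol a [stimulus_protocol()].
#' @return list with matrices `dF` and `dF_smoothed`.
#' @export
compute_dF_image <- function(ts, protocol) {
  stopifnot(inherits(ts, "time_series"), inherits(protocol, "stimulus_protocol"))
  nT <- dim(ts$data)[3]
  on <- protocol$onset_frame
  stim_idx <- on:(on + protocol$stim_avg_frames - 1L)
  base_idx <- (on - protocol$pre_frames):(on - 1L)
  if (max(stim_idx) > nT || min(base_idx) < 1)
    abort("protocol frame indices outside the series")
  stim <- apply(ts$data[, , stim_idx, drop = FALSE], c(1, 2), mean)
  base <- apply(ts$data[, , base_idx, drop = FALSE], c(1, 2), mean)
  dF <- stim - base
  list(dF = dF, dF_smoothed = box_smooth_3x3(dF))
}

# 3x3 unweighted mean with edge-renormalisation
box_smooth_3x3 <- function(m) {
  d <- dim(m)
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
    yt <- ys - dy
    xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
    xt <- xs - dx
    acc[yt, xt] <- acc[yt, xt] + m[ys, xs]
    cnt[yt, xt] <- cnt[yt, xt] + 1
  }
  acc / cnt
}

#' Fluorescence trace of a circular ROI
#'
#' `F(t)` is the mean intensity over the pixels whose centres fall inside a
#' circle of the given diameter (default 2 µm); `F0` averages the
#' `pre_frames` baseline frames of `F(t)`; `dFF = (F - F0)/F0`.
#'
#' @param ts a (background-subtracted) [time_series].
#' @param center `c(x, y)` in µm.
#' @param diameter ROI diameter, µm.
#' @param protocol a [stimulus_protocol()].
#' @return one-row tibble with `x`, `y`, `diameter`, `F0`, `valid` and
#'   list-columns `F` and `dFF`.
#' @export
roi_trace <- function(ts, center, diameter = 2, protocol = stimulus_protocol()) {
  stopifnot(inherits(ts, "time_series"))
  d <- dim(ts$data)
  ax <- voxel_axes(c(d[1], d[2], 1),
                   c(x = ts$pixel_size[["x"]], y = ts$pixel_size[["y"]], z = 1))
  msk <- outer((ax$y - center[["y"]])^2, (ax$x - center[["x"]])^2, "+") <=
    (diameter / 2)^2
  if (!any(msk)) abort("ROI contains no pixels")
  ymin <- min(ax$y[apply(msk, 1, any)]); ymax <- max(ax$y[apply(msk, 1, any)])
  if (center[["x"]] - diameter / 2 < 0 || center[["y"]] - diameter / 2 < 0 ||
      center[["x"]] + diameter / 2 > d[2] * ts$pixel_size[["x"]] ||
      center[["y"]] + diameter / 2 > d[1] * ts$pixel_size[["y"]])
    abort("ROI extends beyond the frame")
  Ft <- vapply(seq_len(d[3]), function(t) mean(ts$data[, , t][msk]), numeric(1))
  base_idx <- (protocol$onset_frame - protocol$pre_frames):(protocol$onset_frame - 1L)
  F0 <- mean(Ft[base_idx])
  valid <- F0 > 0
  dFF <- if (valid) (Ft - F0) / F0 else rep(NA_real_, length(Ft))
  if (!valid) warn("F0 <= 0: trace flagged invalid")
  tibble(x = center[["x"]], y = center[["y"]], diameter = diameter,
         F0 = F0, valid = valid, F = list(Ft), dFF = list(dFF))
}

#' Peak stimulus-evoked dF/F
#'
#' Finds the within-stimulus-window peak of `dFF` and averages the three
#' frames starting there (shifted back when the peak falls in the last two
#' window frames so that three frames fit).
#'
#' @param trace a [roi_trace()] row, or a numeric `dFF` vector.
#' @param protocol a [stimulus_protocol()].
#' @return list with `value` and `frames_used` (3 consecutive indices).
#' @export
dFmax_over_F0 <- function(trace, protocol) {
  dFF <- if (is.numeric(trace)) trace else {
    if (!isTRUE(trace$valid[1])) abort("invalid trace (F0 <= 0)")
    trace$dFF[[1]]
  }
  on <- protocol$onset_frame
  win <- on:min(on + protocol$duration_frames - 1L, length(dFF))
  k <- protocol$stim_avg_frames
  t_peak <- win[which.max(dFF[win])]
  start <- min(t_peak, max(win) - k + 1L)
  frames <- start:(start + k - 1L)
  list(value = mean(dFF[frames]), frames_used = frames)
}

#' Assign ROI classes from the structural channel only
#'
#' Classifies each ROI as `with_syribbon` when its disc overlaps any
#' structural punctum, and `without_syribbon` otherwise. The function sees
#' only ROI centres and the structural puncta (never the indicator
#' channel), enforcing blinded assignment.
#'
#' @param roi_centers tibble with `x`, `y` (µm).
#' @param syribbon_spots tibble with `x`, `y` and radius column `r` (µm),
#'   e.g. peripherally detected RIBEYE spots projected to the imaging plane.
#' @param roi_diameter ROI diameter, µm.
#' @return `roi_centers` with an added `class` column.
#' @export
assign_roi_classes <- function(roi_centers, syribbon_spots, roi_diameter = 2) {
  cls <- vapply(seq_len(nrow(roi_centers)), function(i) {
    if (!nrow(syribbon_spots)) return("without_syribbon")
    dd <- sqrt((syribbon_spots$x - roi_centers$x[i])^2 +
               (syribbon_spots$y - roi_centers$y[i])^2)
    if (any(dd <= roi_diameter / 2 + syribbon_spots$r)) "with_syribbon"
    else "without_syribbon"
  }, character(1))
  roi_centers |> mutate(class = cls)
}

#' Paired comparison of ROI groups across cells
#'
#' Per cell, averages `dfmax` per ROI class; across cells, runs a paired
#' two-sided t-test on (with - without) and reports the mean percent
#' difference `mean(with/without - 1) * 100`.
#'
#' @param roi_table tibble with columns `cell_id`, `class`
#'   (`with_syribbon` / `without_syribbon`) and `dfmax`.
#' @return one-row tibble with `n_cells`, `mean_with`, `mean_without`,
#'   `percent_difference`, `statistic`, `p.value` and list-column
#'   `per_cell`.
#' @export
compare_roi_groups <- function(roi_table) {
  per_cell <- roi_table |>
    group_by(.data$cell_id, .data$class) |>
    summarise(mean_dfmax = mean(.data$dfmax), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "mean_dfmax")
  if (!all(c("with_syribbon", "without_syribbon") %in% names(per_cell)) ||
      anyNA(per_cell$with_syribbon) || anyNA(per_cell$without_syribbon))
    abort("every cell must contribute at least one ROI of each class")
  if (nrow(per_cell) < 2)
    abort("paired test undefined for a single cell")
  diffs <- per_cell$with_syribbon - per_cell$without_syribbon
  tt <- if (all(diffs == 0)) list(statistic = c(t = 0), p.value = 1)
        else t.test(per_cell$with_syribbon, per_cell$without_syribbon, paired = TRUE)
  tibble(n_cells = nrow(per_cell),
         mean_with = mean(per_cell$with_syribbon),
         mean_without = mean(per_cell$without_syribbon),
         percent_difference =
           mean(per_cell$with_syribbon / per_cell$without_syribbon - 1) * 100,
         statistic = unname(tt$statistic), p.value = tt$p.value,
         per_cell = list(per_cell))
}
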