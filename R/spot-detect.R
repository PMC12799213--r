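#' Detection parameters for 3D spot segmentation
#'
#' Mirrors the surface-detection settings used for volumetric fits of
#' RIBEYE/Bassoon/CaV1.3 puncta: a surface-detail smoothing scale of
#' 0.16 µm, channel-specific rolling-ball diameters (RIBEYE 0.3, Bassoon
#' 0.1, CaV1.3 0.08 µm), a 10-voxel minimum size and 0.02-2 µm³ volume
#' bounds.
#'
#' @param surface_detail Gaussian smoothing scale before thresholding, µm.
#' @param background_sphere_diameter rolling-ball diameter, µm; `NULL`
#'   skips background subtraction.
#' @param threshold `"otsu"` for automatic thresholding or an absolute
#'   intensity value.
#' @param min_voxels minimum component size in voxels.
#' @param volume_bounds inclusive `(min, max)` volume bounds, µm³.
#' @param connectivity 6, 18 or 26.
#' @return a `detection_params` list.
#' @export
detection_params <- function(surface_detail = 0.16,
                             background_sphere_diameter = NULL,
                             threshold = "otsu", min_voxels = 10L,
                             volume_bounds = c(0.02, 2.0),
                             connectivity = 26L) {
  if (min_voxels < 1) abort("`min_voxels` must be >= 1")
  if (volume_bounds[1] >= volume_bounds[2]) abort("volume bounds must satisfy min < max")
  if (!connectivity %in% c(6L, 18L, 26L)) abort("connectivity must be 6, 18 or 26")
  structure(list(surface_detail = surface_detail,
                 background_sphere_diameter = background_sphere_diameter,
                 threshold = threshold, min_voxels = as.integer(min_voxels),
                 volume_bounds = volume_bounds,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of one channel by a grayscale opening with a
#' disc of the stated physical diameter, applied per z-plane, and subtracts
#' it; negative residuals are clipped to zero.
#'
#' @param stack an [image_stack].
#' @param channel channel label or index.
#' @param sphere_diameter ball diameter, µm.
#' @return the stack with the channel replaced by its residual.
#' @export
subtract_background <- function(stack, channel, sphere_diameter) {
  stopifnot(inherits(stack, "image_stack"))
  if (sphere_diameter <= 0) abort("`sphere_diameter` must be positive")
  px <- stack$voxel_size[["x"]]
  diam_px <- round(sphere_diameter / px)
  if (diam_px < 1) {
    warn("background ball smaller than one voxel; returning input unchanged")
    return(stack)
  }
  if (diam_px %% 2 == 0) diam_px <- diam_px + 1
  brush <- EBImage::makeBrush(diam_px, shape = "disc")
  arr <- get_channel(stack, channel)
  pad <- diam_px  # replicate edges so the opening is unbiased at borders
  for (zi in seq_len(dim(arr)[3])) {
    pl <- arr[, , zi]
    d2 <- dim(pl)
    yi <- c(rep(1L, pad), seq_len(d2[1]), rep(d2[1], pad))
    xi <- c(rep(1L, pad), seq_len(d2[2]), rep(d2[2], pad))
    mx <- max(pl, 1e-12)  # EBImage grayscale morphology works on [0, 1]
    bg <- EBImage::opening(pl[yi, xi] / mx, brush)[pad + seq_len(d2[1]),
                                                   pad + seq_len(d2[2])] * mx
    arr[, , zi] <- pmax(pl - bg, 0)
  }
  stack$data[, , , channel] <- arr
  stack
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Detect 3D spots in one channel
#'
#' Pipeline: rolling-ball background subtraction (optional), Gaussian
#' smoothing at the surface-detail scale, thresholding (Otsu or absolute),
#' connected-component labelling, removal of components below the minimum
#' voxel count, and per-component morphometry. Replaces an interactive
#' surface-detection stage with deterministic parameters.
#'
#' @param stack an [image_stack].
#' @param channel channel label or index.
#' @param params a [detection_params()].
#' @return tibble of spots sorted by descending volume with columns `id`,
#'   `channel`, `voxel_count`, `volume`, `surface_area`, `sphericity`,
#'   `x`, `y`, `z` (centroid, µm) and list-columns `voxels` (linear indices
#'   into the channel array) and `boundary` (n x 3 matrix of boundary voxel
#'   centres, µm). The label array is attached as attribute `label_map`.
#' @export
detect_spots <- function(stack, channel, params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "detection_params"))
  if (!is.null(params$background_sphere_diameter))
    stack <- subtract_background(stack, channel, params$background_sphere_diameter)
  arr <- get_channel(stack, channel)
  vs <- stack$voxel_size
  if (params$surface_detail > 0) {
    sig <- c(y = params$surface_detail / vs[["y"]],
             x = params$surface_detail / vs[["x"]],
             z = params$surface_detail / vs[["z"]])
    arr <- smooth_gaussian(arr, sig)
  }
  if (all(arr == 0)) {
    out <- empty_spot_tibble(channel)
    attr(out, "label_map") <- array(0L, dim(arr))
    return(out)
  }
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(as.numeric(arr))
         else as.numeric(params$threshold)
  mask <- arr > thr
  labels <- .cc_label_3d(as.logical(mask), dim(arr), params$connectivity)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts >= params$min_voxels)
  if (!length(keep)) {
    out <- empty_spot_tibble(channel)
    attr(out, "label_map") <- labels
    return(out)
  }
  rows <- purrr::map(seq_along(keep), function(i) {
    m <- measure_spot(labels, keep[i], vs)
    tibble(id = i, channel = as.character(channel),
           voxel_count = m$voxel_count, volume = m$volume,
           surface_area = m$surface_area, sphericity = m$sphericity,
           x = m$centroid[["x"]], y = m$centroid[["y"]], z = m$centroid[["z"]],
           voxels = list(m$voxels), boundary = list(m$boundary))
  })
  out <- bind_rows(rows) |> arrange(dplyr::desc(.data$volume)) |>
    mutate(id = dplyr::row_number())
  attr(out, "label_map") <- labels
  out
}

empty_spot_tibble <- function(channel) {
  tibble(id = integer(), channel = as.character(channel), voxel_count = integer(),
         volume = numeric(), surface_area = numeric(), sphericity = numeric(),
         x = numeric(), y = numeric(), z = numeric(),
         voxels = list(), boundary = list())
}
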