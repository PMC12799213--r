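#' Multi-channel 3D image stack
#'
#' Container for confocal-like voxel data. The array is indexed
#' `[y, x, z, channel]` (matching the row/column layout of TIFF pages) and
#' carries the physical voxel size in micrometres so all downstream
#' measurements are reported in physical units.
#'
#' @param data numeric 4D array `[y, x, z, channel]`, or a 3D array for a
#'   single channel.
#' @param voxel_size named numeric vector `c(x =, y =, z =)` in µm.
#' @param channels character vector of channel labels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size = c(x = 0.08, y = 0.08, z = 0.2),
                        channels = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) abort("`data` must be a 3D or 4D array")
  vs <- voxel_size
  if (is.null(names(vs))) names(vs) <- c("x", "y", "z")
  vs <- vs[c("x", "y", "z")]
  if (any(!is.finite(vs)) || any(vs <= 0)) abort("voxel sizes must be positive")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[4]))
  if (length(channels) != dim(data)[4]) abort("one label per channel required")
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(list(data = data, voxel_size = vs, channels = channels),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d channel(s): %s\n",
              d[2], d[1], d[3], d[4], paste(x$channels, collapse = ", ")))
  cat(sprintf("  voxel size (um): x=%g y=%g z=%g\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  invisible(x)
}

#' Extract one channel of an image stack as a 3D array
#'
#' @param stack an [image_stack].
#' @param channel channel label or index.
#' @return numeric 3D array `[y, x, z]`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    if (!channel %in% stack$channels)
      abort(sprintf("channel '%s' not found (have: %s)", channel,
                    paste(stack$channels, collapse = ", ")))
  }
  stack$data[, , , channel, drop = TRUE]
}

# voxel centre coordinates (um) along each axis of a [y, x, z] array
voxel_axes <- function(dims, voxel_size) {
  list(y = (seq_len(dims[1]) - 0.5) * voxel_size[["y"]],
       x = (seq_len(dims[2]) - 0.5) * voxel_size[["x"]],
       z = (seq_len(dims[3]) - 0.5) * voxel_size[["z"]])
}

# truncated, edge-renormalised Gaussian smoothing matrix for one axis
gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  idx <- seq_len(n)
  halfw <- ceiling(4 * sigma)
  K <- outer(idx, idx, function(i, j) {
    w <- exp(-(i - j)^2 / (2 * sigma^2))
    w[abs(i - j) > halfw] <- 0
    w
  })
  K / rowSums(K)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr numeric 3D array `[y, x, z]`.
#' @param sigma_vox per-axis standard deviation in voxels, named or in
#'   `(y, x, z)` order; a scalar is recycled.
#' @return smoothed array of the same shape.
#' @export
smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  if (!is.null(names(sigma_vox))) sigma_vox <- sigma_vox[c("y", "x", "z")]
  K <- gauss_smoother(d[1], sigma_vox[1])
  if (!is.null(K)) arr <- array(K %*% matrix(arr, d[1]), d)
  K <- gauss_smoother(d[2], sigma_vox[2])
  if (!is.null(K)) {
    ap <- aperm(arr, c(2, 1, 3))
    ap <- array(K %*% matrix(ap, d[2]), dim(ap))
    arr <- aperm(ap, c(2, 1, 3))
  }
  K <- gauss_smoother(d[3], sigma_vox[3])
  if (!is.null(K)) {
    ap <- aperm(arr, c(3, 2, 1))
    ap <- array(K %*% matrix(ap, d[3]), dim(ap))
    arr <- aperm(ap, c(3, 2, 1))
  }
  arr
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z-fastest within channel. Physical voxel sizes, channel
#' labels and (for time series) frame times go to `<file>.json` so that a
#' round trip through [read_stack_tiff()] preserves the physical geometry.
#'
#' @param stack an [image_stack].
#' @param file output path (`.tif`).
#' @export
write_stack_tiff <- function(stack, file) {
  d <- dim(stack$data)
  mx <- max(stack$data)
  pages <- list()
  for (ci in seq_len(d[4]))
    for (zi in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- stack$data[, , zi, ci] / max(mx, 1)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  meta <- list(voxel_size = as.list(stack$voxel_size),
               channels = stack$channels,
               shape_zyx = c(d[3], d[1], d[2]),
               intensity_scale = mx)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param file path to the TIFF; `<file>.json` must sit next to it.
#' @return An [image_stack].
#' @export
read_stack_tiff <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  nz <- meta$shape_zyx[1]
  nc <- length(meta$channels)
  d <- c(dim(pages[[1]]), nz, nc)
  arr <- array(0, d)
  k <- 1L
  for (ci in seq_len(nc))
    for (zi in seq_len(nz)) {
      arr[, , zi, ci] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  image_stack(arr, unlist(meta$voxel_size), meta$channels)
}
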