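#' Ground-truth spot table
#'
#' One row per punctum to be rendered. Shapes are axis-aligned ellipsoids
#' (spheres when all semi-axes agree); `placement = "membrane"` declares a
#' punctum anchored near the cell boundary, which
#' [generate_cell_stack()] validates.
#'
#' @param channel channel label per spot.
#' @param x,y,z centre coordinates, µm.
#' @param rx,ry,rz semi-axes, µm.
#' @param intensity rendered peak intensity (a.u.).
#' @param placement `"membrane"` or `"cytosol"`.
#' @param partner_id optional id of a paired spot (NA when unpaired).
#' @param gap requested boundary-to-boundary gap to the membrane shell (for
#'   membrane placement) or to the partner, µm.
#' @return tibble with one row per spot plus derived `true_volume` and
#'   `true_sphericity`.
#' @export
spot_table <- function(channel, x, y, z, rx, ry = rx, rz = rx,
                       intensity = 100, placement = "cytosol",
                       partner_id = NA_integer_, gap = 0) {
  tb <- tibble(id = seq_along(x), channel = channel,
               x = x, y = y, z = z, rx = rx, ry = ry, rz = rz,
               intensity = intensity, placement = placement,
               partner_id = partner_id, gap = gap)
  if (any(tb$rx <= 0 | tb$ry <= 0 | tb$rz <= 0)) abort("semi-axes must be > 0")
  if (any(tb$gap < 0)) abort("gap must be >= 0")
  tb$true_volume <- 4 / 3 * pi * tb$rx * tb$ry * tb$rz
  tb$true_sphericity <- ellipsoid_sphericity(tb$rx, tb$ry, tb$rz)
  tb
}

# Wadell sphericity of an ellipsoid (Thomsen approximation for the area)
ellipsoid_sphericity <- function(a, b, c) {
  p <- 1.6075
  area <- 4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
  vol <- 4 / 3 * pi * a * b * c
  pi^(1 / 3) * (6 * vol)^(2 / 3) / area
}

# occupancy-fraction rendering of one ellipsoid into an accumulator array,
# antialiased by sub (e.g. 3) subsamples per voxel edge
render_ellipsoid <- function(acc, center, semi, intensity, voxel_size, sub = 3L) {
  d <- dim(acc)
  ax <- voxel_axes(d, voxel_size)
  pad <- 1
  ix <- which(abs(ax$x - center[["x"]]) <= semi[["x"]] + pad * voxel_size[["x"]])
  iy <- which(abs(ax$y - center[["y"]]) <= semi[["y"]] + pad * voxel_size[["y"]])
  iz <- which(abs(ax$z - center[["z"]]) <= semi[["z"]] + pad * voxel_size[["z"]])
  if (!length(ix) || !length(iy) || !length(iz)) return(acc)
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  frac <- array(0, c(length(iy), length(ix), length(iz)))
  for (ox in off) for (oy in off) for (oz in off) {
    u <- (ax$x[ix] + ox * voxel_size[["x"]] - center[["x"]]) / semi[["x"]]
    v <- (ax$y[iy] + oy * voxel_size[["y"]] - center[["y"]]) / semi[["y"]]
    w <- (ax$z[iz] + oz * voxel_size[["z"]] - center[["z"]]) / semi[["z"]]
    inside <- outer(outer(v^2, u^2, "+"), w^2, "+") <= 1
    frac <- frac + inside
  }
  acc[iy, ix, iz] <- acc[iy, ix, iz] + intensity * frac / sub^3
  acc
}

# scaled radial coordinate of the config ellipsoid at every voxel centre
cell_rho <- function(config) {
  d <- config$stack_shape
  ax <- voxel_axes(c(d[["y"]], d[["x"]], d[["z"]]), config$voxel_size)
  u2 <- ((ax$x - config$cell_center[["x"]]) / config$cell_semiaxes[["x"]])^2
  v2 <- ((ax$y - config$cell_center[["y"]]) / config$cell_semiaxes[["y"]])^2
  w2 <- ((ax$z - config$cell_center[["z"]]) / config$cell_semiaxes[["z"]])^2
  outer(outer(v2, u2, "+"), w2, "+")
}

# binary inside-cell mask and membrane shell mask for a config
cell_masks <- function(config) {
  inside <- cell_rho(config) <= 1
  sp <- config$voxel_size[c("y", "x", "z")]
  din <- .edt_3d(!inside, dim(inside), sp)  # distance to nearest outside voxel
  shell <- inside & din <= config$membrane_thickness
  list(inside = inside, shell = shell)
}

apply_noise <- function(arr, config) {
  if (!is.null(config$gain) && config$gain > 0)
    arr[] <- rpois(length(arr), pmax(arr, 0) / config$gain) * config$gain
  if (config$read_sd > 0)
    arr[] <- arr + rnorm(length(arr), 0, config$read_sd)
  pmax(arr, 0)
}

#' Generate a multi-channel synthetic cell stack
#'
#' Renders an ellipsoidal cell membrane shell channel plus one channel per
#' distinct spot channel label. Each punctum is rendered as its analytic
#' ellipsoid (occupancy-antialiased), convolved with the Gaussian PSF, and
#' degraded with Poisson + Gaussian noise. Fixing `config$seed` makes the
#' output byte-identical across runs.
#'
#' @param config a [sim_config()].
#' @param spots a [spot_table()]; may have zero rows.
#' @param psf apply the PSF blur (disable for digitization oracles).
#' @param noise apply the noise model.
#' @return list with `stack` (an [image_stack] whose first channel is
#'   `"membrane"`) and `truth` (the spot table as rendered).
#' @export
generate_cell_stack <- function(config, spots = spot_table(character(), numeric(),
                                                           numeric(), numeric(), numeric()),
                                psf = TRUE, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  d <- c(config$stack_shape[["y"]], config$stack_shape[["x"]], config$stack_shape[["z"]])
  masks <- cell_masks(config)

  # membrane-placement validation: spot must sit inside the cell, close to
  # the boundary (within shell + gap + its own extent, one voxel slack)
  if (nrow(spots)) {
    rho <- sqrt(pmax(((spots$x - config$cell_center[["x"]]) / config$cell_semiaxes[["x"]])^2 +
                     ((spots$y - config$cell_center[["y"]]) / config$cell_semiaxes[["y"]])^2 +
                     ((spots$z - config$cell_center[["z"]]) / config$cell_semiaxes[["z"]])^2, 0))
    rmin <- min(config$cell_semiaxes)
    depth <- (1 - rho) * rmin  # lower bound on distance to the boundary
    rmax_spot <- pmax(spots$rx, spots$ry, spots$rz)
    bad_out <- spots$placement == "membrane" & rho > 1
    bad_deep <- spots$placement == "membrane" &
      depth > config$membrane_thickness + spots$gap + 2 * rmax_spot +
        max(config$voxel_size)
    if (any(bad_out))
      abort(sprintf("membrane-placed spot(s) %s lie outside the cell",
                    paste(spots$id[bad_out], collapse = ", ")))
    if (any(bad_deep))
      abort(sprintf("membrane-placed spot(s) %s are too deep in the cytosol",
                    paste(spots$id[bad_deep], collapse = ", ")))
  }

  channels <- c("membrane", unique(spots$channel))
  arr <- array(0, c(d, length(channels)))
  arr[, , , 1] <- masks$shell * config$membrane_intensity
  if (nrow(spots)) {
    for (ci in seq_along(channels)[-1]) {
      acc <- array(0, d)
      rows <- spots[spots$channel == channels[ci], ]
      for (k in seq_len(nrow(rows)))
        acc <- render_ellipsoid(acc,
                                c(x = rows$x[k], y = rows$y[k], z = rows$z[k]),
                                c(x = rows$rx[k], y = rows$ry[k], z = rows$rz[k]),
                                rows$intensity[k], config$voxel_size)
      arr[, , , ci] <- acc
    }
  }
  if (psf && any(config$psf_sigma > 0)) {
    sig_vox <- c(y = config$psf_sigma[["y"]] / config$voxel_size[["y"]],
                 x = config$psf_sigma[["x"]] / config$voxel_size[["x"]],
                 z = config$psf_sigma[["z"]] / config$voxel_size[["z"]])
    for (ci in seq_along(channels))
      arr[, , , ci] <- smooth_gaussian(arr[, , , ci], sig_vox)
  }
  if (noise)
    arr <- with_seed(config$seed, {
      for (ci in seq_along(channels)) arr[, , , ci] <- apply_noise(arr[, , , ci], config)
      arr
    })
  list(stack = image_stack(arr, config$voxel_size, channels), truth = spots)
}

#' Place membrane-anchored punctum pairs for simulation
#'
#' Distributes `n` pairs of puncta (a reference, Bassoon-like, punctum close
#' under the membrane and a query, RIBEYE-like, punctum stacked on it toward
#' the cell interior) at quasi-random directions on the upper hemisphere of
#' the cell ellipsoid.
#'
#' @param config a [sim_config()].
#' @param n number of pairs.
#' @param r_query,r_ref sphere radii, µm. Vectors of length `n` are allowed.
#' @param pair_gap boundary-to-boundary gap between query and reference, µm.
#' @param query_channel,ref_channel channel labels.
#' @param seed RNG seed for the placement directions.
#' @return a [spot_table()] with `2n` rows; queries carry `partner_id` of
#'   their reference.
#' @export
membrane_spot_pairs <- function(config, n, r_query = 0.35, r_ref = 0.3,
                                pair_gap = 0.02, query_channel = "ribeye",
                                ref_channel = "bassoon", seed = config$seed) {
  r_query <- rep_len(r_query, n); r_ref <- rep_len(r_ref, n)
  pair_gap <- rep_len(pair_gap, n)
  dirs <- with_seed(seed, {
    # stratified azimuths keep neighbouring pairs from colliding; shallow
    # polar angles alternating between hemispheres avoid the poles and
    # spread pairs over the whole equatorial belt
    phi <- 2 * pi * (seq_len(n) - 1 + runif(n, 0.2, 0.8)) / n
    cosp <- runif(n, 0.1, 0.5) * rep_len(c(1, -1), n)
    cbind(cos(phi) * sqrt(1 - cosp^2), sin(phi) * sqrt(1 - cosp^2), cosp)
  })
  a <- config$cell_semiaxes
  ref <- query <- vector("list", n)
  for (k in seq_len(n)) {
    u <- dirs[k, ]
    # radius of the ellipsoid along direction u
    rad <- 1 / sqrt(sum((u / a)^2))
    s <- config$cell_center + rad * u
    c_ref <- s - u * (config$membrane_thickness + r_ref[k])
    c_query <- c_ref - u * (r_ref[k] + pair_gap[k] + r_query[k])
    ref[[k]] <- c_ref; query[[k]] <- c_query
  }
  ref <- do.call(rbind, ref); query <- do.call(rbind, query)
  tb <- spot_table(channel = c(rep(ref_channel, n), rep(query_channel, n)),
                   x = c(ref[, 1], query[, 1]),
                   y = c(ref[, 2], query[, 2]),
                   z = c(ref[, 3], query[, 3]),
                   rx = c(r_ref, r_query),
                   placement = "membrane",
                   gap = c(rep(0, n), pair_gap))
  tb$partner_id <- c(rep(NA_integer_, n), seq_len(n))
  tb
}
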