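# Fixture builders and independent oracles shared across the suite.

# digitize an analytic sphere (centre-of-voxel membership) into a padded
# logical array; returns the mask and its grid spacing
digitize_sphere <- function(r, voxel_size = c(x = 0.08, y = 0.08, z = 0.2),
                            pad = 5L) {
  n <- ceiling(2 * r / voxel_size[c("y", "x", "z")]) + 2L * pad
  ax <- lapply(seq_len(3), function(i)
    (seq_len(n[i]) - (n[i] + 1) / 2) * voxel_size[c("y", "x", "z")][i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  list(mask = array(r2 <= r^2, n), voxel_size = voxel_size)
}

digitize_cuboid <- function(half, voxel_size, pad = 5L) {
  n <- ceiling(2 * half / voxel_size[c("y", "x", "z")]) + 2L * pad
  ax <- lapply(seq_len(3), function(i)
    (seq_len(n[i]) - (n[i] + 1) / 2) * voxel_size[c("y", "x", "z")][i])
  h <- half[c("y", "x", "z")]
  inside <- outer(outer(abs(ax[[1]]) <= h[1], abs(ax[[2]]) <= h[2], "&"),
                  abs(ax[[3]]) <= h[3], "&")
  list(mask = array(inside, n), voxel_size = voxel_size)
}

# brute-force voxel-face surface area (oracle; biases digitized-sphere
# areas high by ~50%, so only used where exactness is expected)
face_count_area <- function(mask, voxel_size) {
  d <- dim(mask)
  vs <- voxel_size[c("x", "y", "z")]
  fy <- vs[["x"]] * vs[["z"]]; fx <- vs[["y"]] * vs[["z"]]; fz <- vs[["x"]] * vs[["y"]]
  padm <- array(FALSE, d + 2L)
  padm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  area <- 0
  idx <- which(padm)
  co <- arrayInd(idx, d + 2L)
  for (k in seq_len(nrow(co))) {
    y <- co[k, 1]; x <- co[k, 2]; z <- co[k, 3]
    area <- area +
      fy * (!padm[y - 1, x, z]) + fy * (!padm[y + 1, x, z]) +
      fx * (!padm[y, x - 1, z]) + fx * (!padm[y, x + 1, z]) +
      fz * (!padm[y, x, z - 1]) + fz * (!padm[y, x, z + 1])
  }
  area
}

# all-pairs nearest-reference scan: independent oracle for
# classify_by_proximity on small instances
brute_force_pairing <- function(query, reference, threshold) {
  partner <- rep(NA_integer_, nrow(query))
  for (i in seq_len(nrow(query))) {
    best <- Inf; best_id <- NA_integer_
    for (j in seq_len(nrow(reference))) {
      A <- query$boundary[[i]]; B <- reference$boundary[[j]]
      dij <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
      if (length(intersect(query$voxels[[i]], reference$voxels[[j]]))) dij <- 0
      if (dij < best || (dij == best && reference$id[j] < best_id))
        { best <- dij; best_id <- reference$id[j] }
    }
    if (best <= threshold) partner[i] <- best_id
  }
  partner
}

# mask -> minimal spot-like row usable by surface_distance()
mask_as_spot <- function(mask, voxel_size) {
  lab <- array(as.integer(mask), dim(mask))
  m <- measure_spot(lab, 1L, voxel_size)
  tibble::tibble(id = 1L, volume = m$volume, voxels = list(m$voxels),
                 boundary = list(m$boundary))
}

# label a shared grid with one analytic sphere per row of (x, y, z, r) and
# return a spot tibble comparable to detect_spots() output
make_sphere_scene <- function(centers, voxel_size, extent) {
  n <- ceiling(extent / voxel_size[c("y", "x", "z")])
  ax <- list(y = (seq_len(n[1]) - 0.5) * voxel_size[["y"]],
             x = (seq_len(n[2]) - 0.5) * voxel_size[["x"]],
             z = (seq_len(n[3]) - 0.5) * voxel_size[["z"]])
  lab <- array(0L, n)
  for (k in seq_len(nrow(centers))) {
    r2 <- outer(outer((ax$y - centers$y[k])^2, (ax$x - centers$x[k])^2, "+"),
                (ax$z - centers$z[k])^2, "+")
    lab[r2 <= centers$r[k]^2] <- k
  }
  purrr::map_dfr(seq_len(nrow(centers)), function(k) {
    m <- measure_spot(lab, k, voxel_size)
    tibble::tibble(id = k, volume = m$volume, x = m$centroid[["x"]],
                   y = m$centroid[["y"]], z = m$centroid[["z"]],
                   voxels = list(m$voxels), boundary = list(m$boundary))
  })
}

# label map with one analytic sphere per call site (for detect-free tests)
sphere_label_map <- function(r, voxel_size = c(x = 0.02, y = 0.02, z = 0.02)) {
  dg <- digitize_sphere(r, voxel_size)
  array(as.integer(dg$mask), dim(dg$mask))
}
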