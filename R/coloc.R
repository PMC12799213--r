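#' Cell geometry: peripheral ring and interior masks
#'
#' Segments the cell outline per z-plane from the membrane channel, fills
#' it, and derives a peripheral ring of the stated physical thickness
#' (default 1 µm) along the inside of the boundary, the enclosed interior
#' (fill minus ring), and the set of central planes (all planes with a
#' cell cross-section except the basal and top plane).
#'
#' @param stack an [image_stack].
#' @param membrane_channel channel carrying the membrane/boundary signal.
#' @param ring_thickness ring thickness, µm (> 0).
#' @param threshold `"otsu"` or an absolute intensity for the membrane mask.
#' @return object of class `cell_geometry` with logical arrays `filled`,
#'   `ring`, `interior` and integer `central_planes`.
#' @export
build_cell_geometry <- function(stack, membrane_channel = "membrane",
                                ring_thickness = 1, threshold = "otsu") {
  stopifnot(inherits(stack, "image_stack"))
  if (ring_thickness <= 0) abort("`ring_thickness` must be positive")
  arr <- get_channel(stack, membrane_channel)
  d <- dim(arr)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(as.numeric(arr))
         else as.numeric(threshold)
  mm <- arr > thr
  filled <- array(FALSE, d)
  for (zi in seq_len(d[3])) {
    pl <- mm[, , zi]
    if (!any(pl)) next
    filled[, , zi] <- EBImage::fillHull(pl) > 0
  }
  nonempty <- which(apply(filled, 3, any))
  if (!length(nonempty)) abort("no cell cross-section found in the membrane channel")
  # closed-contour check: the fill of a closed shell strictly exceeds it
  enclosed <- sapply(nonempty, function(zi) sum(filled[, , zi]) > sum(mm[, , zi]))
  if (!any(enclosed))
    abort("membrane contour does not enclose an interior (open contour?)")
  sp <- stack$voxel_size[c("y", "x", "z")]
  # inward distance per plane (z pass suppressed by running plane-wise)
  ring <- array(FALSE, d); interior <- array(FALSE, d)
  for (zi in nonempty) {
    pl <- filled[, , zi, drop = FALSE]
    din <- .edt_3d(!pl, dim(pl), sp)
    r <- pl & din <= ring_thickness
    ring[, , zi] <- r
    interior[, , zi] <- pl & !r
  }
  central <- setdiff(nonempty, range(nonempty))
  if (length(central) < 3)
    warn(sprintf("only %d central plane(s); at least 3 are recommended",
                 length(central)))
  structure(list(filled = filled, ring = ring, interior = interior,
                 central_planes = central, ring_thickness = ring_thickness,
                 voxel_size = stack$voxel_size),
            class = "cell_geometry")
}

#' Peripherality ratio of a channel
#'
#' Per plane, the ratio of the mean pixel intensity in the peripheral ring
#' to the mean intensity of the enclosed interior; the per-cell value is
#' the average over the central planes. Ratios above 1 indicate
#' membrane-enriched signal.
#'
#' @param stack an [image_stack].
#' @param channel channel to score.
#' @param geometry a [build_cell_geometry()] result.
#' @return one-row tibble with `ratio`, `n_planes` and list-column
#'   `per_plane` (plane, ring mean, interior mean, ratio).
#' @export
peripheral_ratio <- function(stack, channel, geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  arr <- get_channel(stack, channel)
  pp <- purrr::map_dfr(geometry$central_planes, function(zi) {
    rv <- mean(arr[, , zi][geometry$ring[, , zi]])
    iv <- mean(arr[, , zi][geometry$interior[, , zi]])
    tibble(plane = zi, ring_mean = rv, interior_mean = iv,
           ratio = ifelse(iv > 0, rv / iv, NA_real_))
  })
  if (anyNA(pp$ratio))
    warn("interior mean is zero in some plane(s); ratio undefined there")
  tibble(ratio = mean(pp$ratio, na.rm = TRUE),
         n_planes = sum(!is.na(pp$ratio)), per_plane = list(pp))
}

#' Pixel-intensity Pearson correlation
#'
#' @param img_a,img_b numeric arrays of identical shape.
#' @param mask optional logical array restricting the voxels used
#'   (at least 10 required).
#' @return Pearson correlation coefficient.
#' @export
pearson_pixel <- function(img_a, img_b, mask = NULL) {
  if (!identical(dim(img_a), dim(img_b))) abort("images must share dimensions")
  a <- if (is.null(mask)) as.numeric(img_a) else img_a[mask]
  b <- if (is.null(mask)) as.numeric(img_b) else img_b[mask]
  if (length(a) < 10) abort("need at least 10 masked voxels")
  cor(a, b)
}

# Costes auto-threshold bisection: largest thresholds, on the orthogonal
# regression line of B on A, for which the sub-threshold Pearson <= 0
costes_auto_thresholds <- function(a, b) {
  fit <- stats::lm(b ~ a)
  slope <- coef(fit)[2]; inter <- coef(fit)[1]
  cand <- sort(unique(quantile(a, probs = seq(1, 0, length.out = 201),
                               names = FALSE)), decreasing = TRUE)
  t_a <- min(a); t_b <- inter + slope * t_a
  for (ta in cand) {
    tb <- inter + slope * ta
    below <- a < ta & b < tb
    if (sum(below) < 10) next
    r <- suppressWarnings(cor(a[below], b[below]))
    if (is.na(r) || r <= 0) { t_a <- ta; t_b <- tb; break }
  }
  c(a = unname(t_a), b = unname(t_b))
}

#' Manders overlap coefficients
#'
#' Thresholded Manders coefficients:
#' `M1 = sum(A_i [B_i > t_B]) / sum(A_i)` and symmetrically `M2`.
#' Thresholds default to the Costes bisection procedure (largest thresholds
#' whose sub-threshold Pearson correlation is non-positive).
#'
#' @param img_a,img_b numeric arrays of identical shape.
#' @param mask optional logical mask.
#' @param thresholds `"auto"` or fixed `c(t_a, t_b)` (>= 0).
#' @return one-row tibble with `m1`, `m2`, `threshold_a`, `threshold_b`.
#' @export
manders <- function(img_a, img_b, mask = NULL, thresholds = "auto") {
  if (!identical(dim(img_a), dim(img_b))) abort("images must share dimensions")
  a <- if (is.null(mask)) as.numeric(img_a) else img_a[mask]
  b <- if (is.null(mask)) as.numeric(img_b) else img_b[mask]
  if (identical(thresholds, "auto")) {
    th <- costes_auto_thresholds(a, b)
  } else {
    if (any(thresholds < 0)) abort("thresholds must be >= 0")
    th <- c(a = thresholds[1], b = thresholds[2])
  }
  m1 <- sum(a[b > th[["b"]]]) / sum(a)
  m2 <- sum(b[a > th[["a"]]]) / sum(b)
  tibble(m1 = m1, m2 = m2, threshold_a = th[["a"]], threshold_b = th[["b"]])
}

#' Costes block-scramble significance test
#'
#' Partitions channel B into square blocks of PSF-scale side, permutes the
#' blocks within the analysis region `n` times, and reports the one-sided
#' p-value: the fraction of scrambles whose Pearson correlation with
#' channel A reaches the observed one.
#'
#' @param img_a,img_b numeric matrices (one plane).
#' @param mask optional logical matrix; blocks with at least half their
#'   pixels inside the mask participate.
#' @param n number of randomizations (default 100; must be >= 1).
#' @param block_px block side in pixels (default 3 x the PSF sigma is a
#'   sensible physical choice; pass it explicitly).
#' @param seed RNG seed for the scrambles.
#' @return one-row tibble with `pearson`, `costes_p`, `n_repetitions` and
#'   `n_blocks`.
#' @export
costes_test <- function(img_a, img_b, mask = NULL, n = 100, block_px = 4L,
                        seed = 1L) {
  if (n < 1) abort("`n` must be >= 1")
  if (!identical(dim(img_a), dim(img_b))) abort("images must share dimensions")
  d <- dim(img_a)
  if (block_px > min(d)) abort("block larger than the image/mask")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  nby <- d[1] %/% block_px; nbx <- d[2] %/% block_px
  blocks <- list()
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    ii <- ((by - 1) * block_px + 1):(by * block_px)
    jj <- ((bx - 1) * block_px + 1):(bx * block_px)
    if (mean(mask[ii, jj]) >= 0.5) blocks[[length(blocks) + 1L]] <- list(ii, jj)
  }
  nb <- length(blocks)
  if (nb < 2) abort("mask too small for block scrambling")
  avec <- unlist(lapply(blocks, function(bl) as.numeric(img_a[bl[[1]], bl[[2]]])))
  bmat <- vapply(blocks, function(bl) as.numeric(img_b[bl[[1]], bl[[2]]]),
                 numeric(block_px^2))
  r_obs <- cor(avec, as.numeric(bmat))
  r_scr <- with_seed(seed, vapply(seq_len(n), function(i) {
    perm <- sample.int(nb)
    cor(avec, as.numeric(bmat[, perm]))
  }, numeric(1)))
  tibble(pearson = r_obs, costes_p = mean(r_scr >= r_obs),
         n_repetitions = as.integer(n), n_blocks = nb)
}

# bilinear interpolation of matrix img (indexed [y, x], pixel centres at
# 0.5, 1.5, ... in pixel units) at physical points (px, py) in pixels
bilinear <- function(img, px, py) {
  d <- dim(img)
  fx <- pmin(pmax(px - 0.5, 0), d[2] - 1)
  fy <- pmin(pmax(py - 0.5, 0), d[1] - 1)
  x0 <- pmin(floor(fx), d[2] - 2); y0 <- pmin(floor(fy), d[1] - 2)
  wx <- fx - x0; wy <- fy - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - wx) * (1 - wy) + img[i01] * wx * (1 - wy) +
    img[i10] * (1 - wx) * wy + img[i11] * wx * wy
}

#' Correlation of intensity profiles along a polyline
#'
#' Resamples the polyline at one-pixel arc-length steps, averages each
#' channel over `width` pixels perpendicular to the local direction, and
#' correlates the two traces (used for tangential line scans along the
#' membrane).
#'
#' @param img_a,img_b numeric matrices (one plane).
#' @param polyline n x 2 matrix of (x, y) vertices in pixel units.
#' @param width perpendicular averaging width in pixels (>= 1).
#' @param pixel_size pixel edge, µm (for the position axis).
#' @return list with `profile` (tibble: position_um, intensity_a,
#'   intensity_b) and `pearson` (NA with a warning for constant traces).
#' @export
line_profile_correlation <- function(img_a, img_b, polyline, width = 3,
                                     pixel_size = 1) {
  if (width < 1) abort("`width` must be >= 1")
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seglen))
  s <- seq(0, max(arc), by = 1)
  pts <- cbind(stats::approx(arc, polyline[, 1], s)$y,
               stats::approx(arc, polyline[, 2], s)$y)
  # local tangent and normal
  tang <- rbind(pts[2, ] - pts[1, ], pts[-1, , drop = FALSE] -
                  pts[-nrow(pts), , drop = FALSE])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  normal <- cbind(-tang[, 2], tang[, 1])
  offs <- seq_len(width) - (width + 1) / 2
  ta <- tb <- numeric(nrow(pts))
  for (o in offs) {
    ta <- ta + bilinear(img_a, pts[, 1] + o * normal[, 1], pts[, 2] + o * normal[, 2])
    tb <- tb + bilinear(img_b, pts[, 1] + o * normal[, 1], pts[, 2] + o * normal[, 2])
  }
  ta <- ta / length(offs); tb <- tb / length(offs)
  r <- if (sd(ta) == 0 || sd(tb) == 0) {
    warn("constant trace: correlation undefined")
    NA_real_
  } else cor(ta, tb)
  list(profile = tibble(position_um = s * pixel_size,
                        intensity_a = ta, intensity_b = tb),
       pearson = r)
}
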