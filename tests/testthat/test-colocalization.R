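make_cell_stack <- function(gain = NULL, read_sd = 0, seed = 1L, ...) {
  cfg <- sim_config(stack_shape = c(y = 80, x = 80, z = 16),
                    cell_semiaxes = c(x = 2.6, y = 2.6, z = 1.4),
                    gain = gain, read_sd = read_sd, seed = seed, ...)
  list(cfg = cfg, out = generate_cell_stack(cfg, psf = FALSE, noise = !is.null(gain)))
}

test_that("cell geometry derives a ring of the requested physical thickness", {
  # spherical mid-plane: the ring area has the closed form pi (a^2 - (a-t)^2)
  mc <- make_cell_stack()
  geom <- build_cell_geometry(mc$out$stack, "membrane", ring_thickness = 1)
  zi <- round(dim(mc$out$stack$data)[3] / 2)
  # mid-plane cross-section radius
  a <- mc$cfg$cell_semiaxes[["x"]]
  ring_area <- sum(geom$ring[, , zi]) * prod(mc$cfg$voxel_size[c("x", "y")])
  analytic <- pi * (a^2 - (a - 1)^2)
  expect_lt(abs(ring_area - analytic) / analytic, 0.05)
  expect_false(any(geom$ring & geom$interior))
  expect_error(build_cell_geometry(mc$out$stack, "membrane", ring_thickness = 0),
               "positive")
})

test_that("too few central planes triggers a warning, open contours an error", {
  arr <- array(0, c(40, 40, 3))
  ax <- (seq_len(40) - 0.5) * 0.08
  rho <- sqrt(outer((ax - 1.6)^2, (ax - 1.6)^2, "+"))
  shell <- rho <= 1.2 & rho >= 1.0
  for (zi in 1:3) arr[, , zi] <- shell * 100
  st <- image_stack(arr, c(x = 0.08, y = 0.08, z = 0.2), "membrane")
  expect_warning(build_cell_geometry(st, "membrane"), "central plane")
  # open contour: a half-arc encloses nothing
  arr2 <- arr
  open_arc <- shell & outer(ax > 1.6, rep(TRUE, 40))
  for (zi in 1:3) arr2[, , zi] <- open_arc * 100
  st2 <- image_stack(arr2, c(x = 0.08, y = 0.08, z = 0.2), "membrane")
  expect_error(suppressWarnings(build_cell_geometry(st2, "membrane")), "enclose")
})

test_that("peripheral ratio is 1 for uniform signal and increases with ring placement", {
  mc <- make_cell_stack()
  st <- mc$out$stack
  geom <- build_cell_geometry(st, "membrane")
  d <- dim(st$data)[1:3]
  uni <- image_stack(array(cbind(st$data[, , , 1], array(50, d)), c(d, 2)),
                     st$voxel_size, c("membrane", "probe"))
  expect_equal(peripheral_ratio(uni, "probe", geom)$ratio, 1, tolerance = 1e-9)
  # signal confined to the ring: ratio far above 1 (interior at small epsilon)
  ring_sig <- array(0.1, d); ring_sig[geom$ring] <- 100
  st_ring <- image_stack(array(cbind(st$data[, , , 1], ring_sig), c(d, 2)),
                         st$voxel_size, c("membrane", "probe"))
  expect_gt(peripheral_ratio(st_ring, "probe", geom)$ratio, 100)
  # membrane-anchored puncta score higher than the same puncta at the centroid
  cfg <- mc$cfg
  ctr <- cfg$cell_center
  # equatorial membrane-anchored puncta sit inside the central-plane rings
  ang <- c(0.3, 1.8, 3.4, 5.1)
  rad <- cfg$cell_semiaxes[["x"]] - cfg$membrane_thickness - 0.35
  mem <- spot_table("ribeye",
                    x = ctr[["x"]] + rad * cos(ang),
                    y = ctr[["y"]] + rad * sin(ang),
                    z = rep(ctr[["z"]], 4), rx = 0.3, placement = "membrane")
  cyto <- mem
  cyto$x <- ctr[["x"]] + (mem$x - ctr[["x"]]) * 0.1
  cyto$y <- ctr[["y"]] + (mem$y - ctr[["y"]]) * 0.1
  cyto$placement <- "cytosol"
  st_mem <- generate_cell_stack(cfg, mem, psf = FALSE, noise = FALSE)$stack
  st_cyt <- generate_cell_stack(cfg, cyto, psf = FALSE, noise = FALSE)$stack
  # small uniform offset emulating residual background everywhere
  st_mem$data[, , , "ribeye"] <- st_mem$data[, , , "ribeye"] + 0.5
  st_cyt$data[, , , "ribeye"] <- st_cyt$data[, , , "ribeye"] + 0.5
  r_mem <- peripheral_ratio(st_mem, "ribeye", geom)$ratio
  r_cyt <- peripheral_ratio(st_cyt, "ribeye", geom)$ratio
  expect_gt(r_mem, r_cyt)
  # global intensity scaling leaves the ratio unchanged
  st_mem2 <- st_mem; st_mem2$data <- st_mem2$data * 7
  expect_equal(peripheral_ratio(st_mem2, "ribeye", geom)$ratio, r_mem,
               tolerance = 1e-12)
})

test_that("pixel Pearson correlation hits closed forms, nulls and affine invariance", {
  set.seed(4)
  a <- matrix(runif(10000), 100)
  expect_equal(pearson_pixel(a, a), 1)
  expect_equal(pearson_pixel(a, 5 - a), -1)
  b <- matrix(runif(10000), 100)
  expect_lt(abs(pearson_pixel(a, b)), 0.05)
  # affine rescaling with positive gain does not change r
  expect_equal(pearson_pixel(3 * a + 2, b), pearson_pixel(a, b), tolerance = 1e-12)
  expect_error(pearson_pixel(a[1:3, 1:3], a[1:3, 1:3]), "at least 10")
})

test_that("Manders coefficients respect identity, disjoint and nested supports", {
  set.seed(5)
  a <- matrix(rlnorm(4096), 64)
  ident <- manders(a, a)
  expect_equal(ident$m1, 1, tolerance = 0.05)
  expect_equal(ident$m2, 1, tolerance = 0.05)
  # disjoint supports with fixed thresholds
  d1 <- matrix(0, 64, 64); d1[1:32, ] <- 10
  d2 <- matrix(0, 64, 64); d2[33:64, ] <- 10
  dj <- manders(d1, d2, thresholds = c(1, 1))
  expect_equal(dj$m1, 0)
  expect_equal(dj$m2, 0)
  # A-support strictly inside B-support: M1 = 1, M2 = covered fraction of B
  n1 <- matrix(0, 64, 64); n1[17:48, 17:48] <- 5
  n2 <- matrix(0, 64, 64); n2[1:64, 1:64] <- 5
  ns <- manders(n1, n2, thresholds = c(1, 1))
  expect_equal(ns$m1, 1)
  expect_equal(ns$m2, 32 * 32 / (64 * 64))
})

test_that("Costes scramble test separates colocalized from independent channels", {
  set.seed(6)
  base <- matrix(0, 64, 64)
  for (k in 1:12) {
    cy <- sample(5:60, 1); cx <- sample(5:60, 1)
    base[cy + (-2:2), cx + (-2:2)] <- base[cy + (-2:2), cx + (-2:2)] + 50
  }
  pos_a <- base + matrix(rnorm(4096, 20, 3), 64)
  pos_b <- 0.8 * base + matrix(rnorm(4096, 15, 3), 64)
  ct <- costes_test(pos_a, pos_b, n = 100, block_px = 4, seed = 2L)
  expect_equal(ct$costes_p, 0)
  expect_gt(ct$pearson, 0.5)
  # independent noise: non-significant in the vast majority of replicates
  p0 <- vapply(1:20, function(k) {
    ind_a <- matrix(rnorm(4096, 20, 5), 64)
    ind_b <- matrix(rnorm(4096, 20, 5), 64)
    costes_test(ind_a, ind_b, n = 100, block_px = 4, seed = k)$costes_p
  }, numeric(1))
  expect_gte(sum(p0 >= 0.05), 16)
  expect_error(costes_test(pos_a, pos_b, n = 0), ">= 1")
  expect_error(costes_test(pos_a, pos_b, block_px = 100), "larger")
})

test_that("line-profile correlation tracks co-positioned vs offset hotspots", {
  n <- 80
  xs <- seq_len(n)
  prof <- function(centers) {
    img <- matrix(1, 40, n)
    for (cc in centers) img <- img + outer(rep(1, 40), 40 * exp(-(xs - cc)^2 / 8))
    img
  }
  a <- prof(c(15, 40, 65))
  b_co <- prof(c(15, 40, 65))
  b_off <- prof(c(27, 52, 77))
  line <- cbind(seq(5, 75, length.out = 30), rep(20, 30))
  res_co <- line_profile_correlation(a, b_co, line, width = 3)
  expect_equal(res_co$pearson, 1, tolerance = 1e-9)
  res_off <- line_profile_correlation(a, b_off, line, width = 3)
  expect_lt(res_off$pearson, 0.3)
  expect_gt(res_co$pearson, 0.8)
  expect_warning(res_flat <- line_profile_correlation(matrix(1, 40, n),
                                                      matrix(1, 40, n),
                                                      line, width = 3),
                 "constant")
  expect_true(is.na(res_flat$pearson))
})
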