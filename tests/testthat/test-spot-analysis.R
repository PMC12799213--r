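vs_paper <- c(x = 0.08, y = 0.08, z = 0.2)

test_that("rolling-ball background subtraction behaves on flat, peaked and sloped inputs", {
  d <- c(40, 40, 2)
  mk <- function(arr) image_stack(array(arr, d), vs_paper, "ch")
  # flat background is removed exactly
  st <- subtract_background(mk(5), "ch", 0.5)
  expect_true(all(get_channel(st, "ch") == 0))
  # compact punctum far below the ball scale survives nearly intact
  arr <- array(0, d)
  arr[19:22, 19:22, 1] <- 100
  st2 <- subtract_background(mk(arr), "ch", 1.0)
  expect_gt(sum(get_channel(st2, "ch")[, , 1]) / sum(arr), 0.95)
  # a smooth gradient is tracked as background
  grad <- array(rep(seq(0, 10, length.out = 40), each = 40), d)
  st3 <- subtract_background(mk(grad), "ch", 0.4)
  expect_lt(max(get_channel(st3, "ch")), 0.05 * 10)
  # ball below one voxel: warning + identity
  expect_warning(st4 <- subtract_background(mk(arr), "ch", 0.01), "smaller")
  expect_identical(get_channel(st4, "ch"), arr)
})

test_that("detection keeps components above the voxel minimum and honours connectivity", {
  arr <- array(0, c(48, 48, 12))
  # five blocks of >= 10 voxels
  origins <- cbind(c(4, 4, 24, 36, 36), c(4, 36, 24, 4, 36))
  for (k in 1:5) {
    oy <- origins[k, 1]; ox <- origins[k, 2]
    arr[oy:(oy + 2), ox:(ox + 2), 4:5] <- 100  # 18 voxels
  }
  # three sub-threshold specks (< 10 voxels)
  arr[14, 14, 8] <- 100
  arr[30, 8, 8:9] <- 100
  arr[8, 30, 8] <- 100
  st <- image_stack(arr, vs_paper, "ch")
  spots <- detect_spots(st, "ch", detection_params(surface_detail = 0, threshold = 50))
  expect_equal(nrow(spots), 5L)
  expect_true(all(spots$voxel_count >= 10))
  # two cubes separated by one empty voxel are distinct at 26-connectivity
  arr2 <- array(0, c(20, 20, 4))
  arr2[3:5, 3:5, 2] <- 100
  arr2[3:5, 7:9, 2] <- 100
  st2 <- image_stack(arr2, vs_paper, "ch")
  p <- detection_params(surface_detail = 0, threshold = 50, min_voxels = 1)
  expect_equal(nrow(detect_spots(st2, "ch", p)), 2L)
  # touching (diagonal contact) merges into one
  arr2[3:5, 6, 2] <- 100
  st3 <- image_stack(arr2, vs_paper, "ch")
  expect_equal(nrow(detect_spots(st3, "ch", p)), 1L)
  # all-zero channel: empty result, not an error
  empty <- detect_spots(image_stack(array(0, c(10, 10, 4)), vs_paper, "ch"), "ch", p)
  expect_equal(nrow(empty), 0L)
})

test_that("morphometry recovers closed-form volume and sphericity at fine resolution", {
  vs_fine <- c(x = 0.02, y = 0.02, z = 0.02)
  lab <- sphere_label_map(0.5, vs_fine)
  m <- measure_spot(lab, 1L, vs_fine)
  expect_lt(abs(m$volume - 4 / 3 * pi * 0.5^3) / (4 / 3 * pi * 0.5^3), 0.02)
  expect_lt(abs(m$sphericity - 1), 0.02)
  # cube: Wadell sphericity pi^(1/3) (6 a^3)^(2/3) / (6 a^2) = 0.8060
  cb <- digitize_cuboid(c(x = 1.0, y = 1.0, z = 1.0), vs_fine)
  mc <- measure_spot(array(as.integer(cb$mask), dim(cb$mask)), 1L, vs_fine)
  expect_lt(abs(mc$sphericity - 0.8060), 0.02)
  # single voxel: exactly one voxel volume
  lab1 <- array(0L, c(5, 5, 5)); lab1[3, 3, 3] <- 1L
  expect_equal(measure_spot(lab1, 1L, vs_paper)$volume, prod(vs_paper))
  expect_error(measure_spot(lab1, 2L, vs_paper), "not present")
})

test_that("sphericity orders sphere > 3:1 ellipsoid > plate at equal volume", {
  vs_fine <- c(x = 0.02, y = 0.02, z = 0.02)
  meas <- function(half) {
    cfg_mask <- digitize_ellipsoid(half, vs_fine)
    measure_spot(array(as.integer(cfg_mask), dim(cfg_mask)), 1L, vs_fine)$sphericity
  }
  digitize_ellipsoid <- function(semi, vs) {
    n <- ceiling(2 * semi[c("y", "x", "z")] / vs[c("y", "x", "z")]) + 10L
    ax <- lapply(1:3, function(i) (seq_len(n[i]) - (n[i] + 1) / 2) * vs[c("y", "x", "z")][i])
    s <- semi[c("y", "x", "z")]
    outer(outer((ax[[1]] / s[1])^2, (ax[[2]] / s[2])^2, "+"), (ax[[3]] / s[3])^2, "+") <= 1
  }
  v0 <- 4 / 3 * pi * 0.4^3
  sph <- meas(c(x = 0.4, y = 0.4, z = 0.4))
  # 3:1 prolate ellipsoid of equal volume: a = 0.4/3^(1/3) * 3, b = c = 0.4/3^(1/3)
  b <- 0.4 / 3^(1 / 3)
  ell <- meas(c(x = 3 * b, y = b, z = b))
  # plate 10:10:1 of equal volume
  pb <- (0.4^3 / 100)^(1 / 3)
  plate <- meas(c(x = 10 * pb, y = 10 * pb, z = pb))
  expect_gt(sph, ell)
  expect_gt(ell, plate)
})

test_that("volume filter is inclusive at both bounds and idempotent", {
  spots <- tibble::tibble(id = 1:5, volume = c(0.01, 0.02, 1.0, 2.0, 2.5))
  f <- filter_spots(spots)
  expect_equal(f$kept$volume, c(0.02, 1.0, 2.0))
  expect_equal(f$rejected$reason, c("too_small", "too_large"))
  # idempotence
  f2 <- filter_spots(f$kept)
  expect_identical(f2$kept, f$kept)
  expect_equal(nrow(f2$rejected), 0L)
  # empty input
  fe <- filter_spots(spots[0, ])
  expect_equal(nrow(fe$kept), 0L)
  expect_equal(nrow(fe$rejected), 0L)
})

test_that("surface distance is symmetric, zero on overlap, and matches analytic gaps", {
  vs_fine <- c(x = 0.04, y = 0.04, z = 0.04)
  mk_sphere_at <- function(cx, r, n = 60) {
    ax <- (seq_len(n) - 0.5) * 0.04
    r2 <- outer(outer((ax - 1.2)^2, (ax - cx)^2, "+"), (ax - 1.2)^2, "+")
    array(r2 <= r^2, c(n, n, n))
  }
  a <- mask_as_spot(mk_sphere_at(0.7, 0.3), vs_fine)
  b <- mask_as_spot(mk_sphere_at(1.7, 0.3), vs_fine)  # analytic gap 1.0 - 0.6 = 0.4
  dab <- surface_distance(a, b)
  diag_vox <- sqrt(sum(vs_fine^2))
  expect_lt(abs(dab - 0.4), diag_vox)
  expect_equal(dab, surface_distance(b, a))
  expect_equal(surface_distance(a, a), 0)
})

test_that("proximity classification matches ground truth and the brute-force scan", {
  vs <- c(x = 0.02, y = 0.02, z = 0.02)
  # two query/reference pairs with analytic boundary gaps 0.03 and 0.40 um
  ref <- tibble::tibble(x = c(0.6, 2.4), y = c(0.6, 0.6), z = c(0.6, 0.6),
                        r = 0.2)
  qry <- tibble::tibble(x = ref$x, y = ref$y + 0.2 + 0.2 + c(0.03, 0.40),
                        z = ref$z, r = 0.2)
  scene <- make_sphere_scene(dplyr::bind_rows(ref, qry), vs, c(3.2, 3.2, 1.2))
  refs <- scene[1:2, ] |> dplyr::mutate(id = 1:2)
  qrys <- scene[3:4, ] |> dplyr::mutate(id = 1:2)
  cl45 <- classify_by_proximity(qrys, refs, 0.045)
  expect_equal(cl45$colocalized, c(TRUE, FALSE))
  expect_equal(cl45$partner_id, c(1L, NA_integer_))
  cl60 <- classify_by_proximity(qrys, refs, 0.06)
  expect_equal(cl60$colocalized, c(TRUE, FALSE))
  # measured gaps track the analytic ones
  expect_lt(abs(cl45$partner_distance[1] - 0.03), 0.02)
  expect_lt(abs(cl45$partner_distance[2] - 0.40), 0.05)
  # brute-force all-pairs oracle agrees on a larger random instance
  set.seed(9)
  many <- tibble::tibble(x = runif(14, 0.4, 2.8), y = runif(14, 0.4, 2.8),
                         z = runif(14, 0.3, 0.9), r = runif(14, 0.08, 0.15))
  scene2 <- make_sphere_scene(many, c(x = 0.04, y = 0.04, z = 0.04),
                              c(3.2, 3.2, 1.2))
  q2 <- scene2[1:7, ] |> dplyr::mutate(id = 1:7)
  r2 <- scene2[8:14, ] |> dplyr::mutate(id = 1:7)
  for (thr in c(0.045, 0.06, 0.3)) {
    cl <- classify_by_proximity(q2, r2, thr)
    expect_equal(cl$partner_id, brute_force_pairing(q2, r2, thr))
  }
  # empty reference: all unpaired
  cl0 <- classify_by_proximity(qrys, refs[0, ], 0.06)
  expect_true(all(!cl0$colocalized))
  # overlapping spots pair at threshold 0
  expect_equal(classify_by_proximity(qrys, qrys, 0)$partner_id, qrys$id)
  expect_error(classify_by_proximity(qrys, refs, -1), ">= 0")
})

test_that("paired-volume correlation hits the closed-form and null cases", {
  mk <- function(v, ids = seq_along(v)) tibble::tibble(id = ids, volume = v,
                                                       partner_id = ids)
  q <- mk(c(0.1, 0.2, 0.3, 0.4)); r <- mk(2 * c(0.1, 0.2, 0.3, 0.4))
  expect_equal(volume_correlation(q, r)$estimate, 1)
  r_anti <- mk(1 - c(0.1, 0.2, 0.3, 0.4))
  expect_equal(volume_correlation(q, r_anti)$estimate, -1)
  set.seed(42)
  qn <- mk(rlnorm(1000)); rn <- mk(rlnorm(1000))
  expect_lt(abs(volume_correlation(qn, rn)$estimate), 0.1)
  expect_error(volume_correlation(mk(1:2), mk(1:2)), "at least 3")
})

test_that("volume recovery on digitized spheres at acquisition voxel size", {
  # spot-check of the parameter-recovery property at reduced n (the full
  # 100-sphere sweep runs in the acceptance suite)
  set.seed(3)
  vols <- exp(seq(log(0.02), log(2), length.out = 20))
  radii <- (3 * vols / (4 * pi))^(1 / 3)
  err <- vapply(radii, function(r) {
    dg <- digitize_sphere(r, vs_paper)
    m <- measure_spot(array(as.integer(dg$mask), dim(dg$mask)), 1L, vs_paper)
    abs(m$volume - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_lt(median(err), 0.15)
})
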