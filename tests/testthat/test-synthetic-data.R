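test_that("noiseless sphere rendering conserves analytic integrated intensity", {
  cfg <- sim_config(stack_shape = c(y = 40, x = 40, z = 20), gain = NULL, read_sd = 0)
  sp <- spot_table("ribeye", x = 1.6, y = 1.6, z = 2, rx = 0.5, intensity = 100)
  out <- generate_cell_stack(cfg, sp, psf = FALSE, noise = FALSE)
  ch <- get_channel(out$stack, "ribeye")
  analytic <- 4 / 3 * pi * 0.5^3 / prod(cfg$voxel_size) * 100
  expect_lt(abs(sum(ch) - analytic) / analytic, 0.02)
  # PSF conserves total intensity too (blur redistributes, does not create)
  out_psf <- generate_cell_stack(cfg, sp, psf = TRUE, noise = FALSE)
  expect_lt(abs(sum(get_channel(out_psf$stack, "ribeye")) - analytic) / analytic, 0.02)
})

test_that("zero spots yields a membrane-shell-only stack", {
  cfg <- sim_config(stack_shape = c(y = 48, x = 48, z = 16), gain = NULL, read_sd = 0)
  out <- generate_cell_stack(cfg, psf = FALSE, noise = FALSE)
  expect_identical(out$stack$channels, "membrane")
  mem <- get_channel(out$stack, "membrane")
  expect_gt(sum(mem > 0), 0)
  # nonzero voxels are exactly the shell: inside the cell, near the boundary
  rho <- ribbonquant:::cell_rho(cfg)
  expect_true(all(rho[mem > 0] <= 1))
  expect_equal(nrow(out$truth), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(stack_shape = c(y = 32, x = 32, z = 10), seed = 7L)
  sp <- spot_table("ribeye", x = 1.3, y = 1.3, z = 1, rx = 0.3)
  a <- generate_cell_stack(cfg, sp)$stack$data
  b <- generate_cell_stack(cfg, sp)$stack$data
  expect_identical(a, b)
  tr <- transient_table(x = 1.3, y = 1.3, onset_frame = 6, duration_frames = 5)
  t1 <- generate_timeseries(cfg, tr, n_frames = 15)$series$data
  t2 <- generate_timeseries(cfg, tr, n_frames = 15)$series$data
  expect_identical(t1, t2)
  r1 <- generate_iv_recording(seed = 7L)$sweeps
  r2 <- generate_iv_recording(seed = 7L)$sweeps
  expect_identical(r1, r2)
})

test_that("membrane placement is validated against the cell geometry", {
  cfg <- sim_config(stack_shape = c(y = 48, x = 48, z = 16))
  ctr <- cfg$cell_center
  # centre of the cell is far too deep for membrane anchoring
  deep <- spot_table("ribeye", x = ctr[["x"]], y = ctr[["y"]], z = ctr[["z"]],
                     rx = 0.2, placement = "membrane")
  expect_error(generate_cell_stack(cfg, deep), "too deep")
  outside <- spot_table("ribeye", x = 0.1, y = 0.1, z = 0.1,
                        rx = 0.2, placement = "membrane")
  expect_error(generate_cell_stack(cfg, outside), "outside the cell")
})

test_that("membrane spot pairs respect the requested gap within a voxel diagonal", {
  cfg <- sim_config(stack_shape = c(y = 96, x = 96, z = 24), gain = NULL, read_sd = 0)
  pairs <- membrane_spot_pairs(cfg, 4, pair_gap = 0.4, seed = 3L)
  out <- generate_cell_stack(cfg, pairs, psf = FALSE, noise = FALSE)
  rib <- detect_spots(out$stack, "ribeye", detection_params(surface_detail = 0, threshold = 50))
  bas <- detect_spots(out$stack, "bassoon", detection_params(surface_detail = 0, threshold = 50))
  expect_equal(nrow(rib), 4L)
  diag_vox <- sqrt(sum(cfg$voxel_size^2))
  for (i in seq_len(nrow(rib))) {
    dmin <- min(vapply(seq_len(nrow(bas)), function(j)
      surface_distance(rib[i, ], bas[j, ]), numeric(1)))
    expect_lt(abs(dmin - 0.4), diag_vox)
  }
})

test_that("Poisson-only noise is unbiased: sample mean within 3 SE of truth", {
  cfg <- sim_config(stack_shape = c(y = 6, x = 6, z = 2), gain = 2, read_sd = 0)
  truth <- array(50, c(6, 6, 2))
  n_draws <- 1000
  acc <- array(0, dim(truth))
  set.seed(11)
  for (i in seq_len(n_draws)) acc <- acc + ribbonquant:::apply_noise(truth, cfg)
  m <- acc / n_draws
  # Var of one draw = gain * signal; SE of the mean over draws
  se <- sqrt(cfg$gain * 50 / n_draws)
  expect_true(all(abs(m - 50) < 3 * se + 1e-9))
})

test_that("time-series transients follow the closed-form course", {
  cfg <- sim_config(stack_shape = c(y = 30, x = 30, z = 4), gain = NULL, read_sd = 0)
  # plateau: decay_tau = Inf, max pixel value F0 + amplitude
  tr <- transient_table(x = 1.2, y = 1.2, F0 = 100, amplitude = 50,
                        onset_frame = 6, duration_frames = 5, decay_tau = Inf)
  s <- generate_timeseries(cfg, tr, n_frames = 15, baseline = 10,
                           psf = FALSE, noise = FALSE)$series
  expect_equal(max(s$data), 150)
  expect_equal(max(s$data[, , 5]), 100)  # pre-stimulus hotspot at F0
  # amplitude 0: flat at F0
  tr0 <- transient_table(x = 1.2, y = 1.2, F0 = 100, amplitude = 0,
                         onset_frame = 6, duration_frames = 5)
  s0 <- generate_timeseries(cfg, tr0, n_frames = 15, psf = FALSE, noise = FALSE)$series
  px <- s0$data[15, 15, ]
  expect_true(all(px == px[1]))
  # finite tau declines within the window, matching the analytic trace
  tau <- 0.2
  trd <- transient_table(x = 1.2, y = 1.2, F0 = 100, amplitude = 50,
                         onset_frame = 6, duration_frames = 5, decay_tau = tau)
  sd_ <- generate_timeseries(cfg, trd, n_frames = 15, psf = FALSE, noise = FALSE)$series
  hot <- sd_$data[15, 15, ]
  expected <- 100 + ribbonquant:::transient_course(50, 6, tau, 15, 20)
  expect_equal(hot, expected, tolerance = 1e-12)
  expect_gt(mean(hot[6:8]), mean(hot[8:10]))  # declining stimulus-window mean
  expect_error(generate_timeseries(cfg, trd, n_frames = 15, frame_rate = 0),
               "frame_rate")
  expect_error(generate_timeseries(cfg, trd, n_frames = 10), "exceed")
})

test_that("IV generator matches the Boltzmann-ohmic closed form", {
  # midpoint: V = vhalf, no leak/noise
  rec <- generate_iv_recording(vhalf = -15, slope_k = 8, g_max = 2, v_rev = 60,
                               leak_conductance = 0, noise_sd = 0,
                               protocol = c(-15 + 21.2, 50), ljp = 21.2)
  iv <- extract_iv(correct_ljp(rec))
  expect_equal(iv$current[1], 2 * (-15 - 60) / 2, tolerance = 1e-9)
  # V = v_rev: leak only
  rec2 <- generate_iv_recording(vhalf = -15, slope_k = 8, g_max = 2, v_rev = 60,
                                leak_conductance = 0.5, noise_sd = 0,
                                protocol = c(60 + 21.2, 85), ljp = 21.2)
  iv2 <- extract_iv(correct_ljp(rec2))
  expect_equal(iv2$current[1], 0.5 * 60, tolerance = 1e-9)
  # full protocol, noiseless: equals closed form at every one of the 30 steps
  rec3 <- generate_iv_recording(noise_sd = 0, leak_conductance = 0.3)
  rec3 <- correct_ljp(rec3)
  iv3 <- extract_iv(rec3)
  expect_length(iv3$voltage, 30)
  expect_equal(range(iv3$voltage), c(-86.2, 58.8))
  closed <- boltzmann_current(iv3$voltage, -15, 8, 2, 60) + 0.3 * iv3$voltage
  expect_equal(iv3$current, closed, tolerance = 1e-9)
  expect_error(generate_iv_recording(slope_k = 0), "slope_k")
  expect_error(generate_iv_recording(protocol = c(0, 0)), "strictly increasing")
})
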