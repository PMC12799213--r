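#' Load and validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list) and fills defaults. Required fields
#' are validated with an error naming the missing/invalid field.
#'
#' @param config path to a YAML file or a named list.
#' @return validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    out_dir = "ribbonquant_run",
    stages = list(simulate = TRUE, segment = TRUE, classify = TRUE,
                  coloc = TRUE, calcium = TRUE, ephys = TRUE, stats = TRUE),
    sim = list(n_pairs = 12, stack = list(y = 96, x = 96, z = 24)),
    detection = list(surface_detail = 0.16, min_voxels = 10,
                     volume_bounds = c(0.02, 2.0), connectivity = 26,
                     background_sphere_diameter = NULL),
    thresholds = list(pairing = 0.06, syribbon = 0.045),
    costes = list(reps = 100, block_px = 4),
    protocol = list(onset_frame = 11, duration_frames = 10,
                    pre_frames = 5, stim_avg_frames = 3)
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$seed)) abort("field `seed` must be numeric")
  for (f in c("pairing", "syribbon"))
    if (!is.numeric(cfg$thresholds[[f]]) || cfg$thresholds[[f]] < 0)
      abort(sprintf("field `thresholds.%s` must be a nonnegative number", f))
  if (cfg$costes$reps < 1) abort("field `costes.reps` must be >= 1")
  if (!is.null(config$input) && !file.exists(config$input))
    abort(sprintf("field `input`: file '%s' does not exist", config$input))
  structure(cfg, class = "run_config")
}

write_stage_csv <- function(df, path, seed, stage) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  con <- file(path, "w")
  writeLines(sprintf("# ribbonquant stage=%s seed=%d", stage, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes the enabled stages in dependency order on seeded synthetic
#' data: simulate a cell stack, segment the two punctum channels, classify
#' pairs by proximity, pixel colocalization on the peripheral ring,
#' stimulus-locked calcium analysis, IV extraction with QC and activation
#' fit, and the statistical comparison of ROI groups. Every output CSV
#' records the seed in its header; a JSON manifest lists inputs, parameter
#' hashes and outputs.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @param seed overrides the config seed.
#' @param out_dir overrides the config output directory.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), seed = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  outputs <- list()
  st <- cfg$stages

  sc <- sim_config(stack_shape = c(y = cfg$sim$stack$y, x = cfg$sim$stack$x,
                                   z = cfg$sim$stack$z), seed = seed)
  spots_truth <- ribeye <- bassoon <- NULL

  if (isTRUE(st$simulate)) {
    pairs <- membrane_spot_pairs(sc, cfg$sim$n_pairs, seed = seed + 11L)
    sim <- generate_cell_stack(sc, pairs)
    stack <- sim$stack
    outputs$truth <- write_stage_csv(sim$truth, file.path(cfg$out_dir, "truth_spots.csv"),
                                     seed, "simulate")
    outputs$stack <- write_stack_tiff(stack, file.path(cfg$out_dir, "stack.tif"))
  } else abort("stage `simulate` is required in the demonstration pipeline")

  if (isTRUE(st$segment)) {
    dp <- detection_params(
      surface_detail = cfg$detection$surface_detail,
      background_sphere_diameter = cfg$detection$background_sphere_diameter,
      min_voxels = cfg$detection$min_voxels,
      volume_bounds = cfg$detection$volume_bounds,
      connectivity = cfg$detection$connectivity)
    ribeye <- filter_spots(detect_spots(stack, "ribeye", dp),
                           cfg$detection$volume_bounds)$kept
    bassoon <- filter_spots(detect_spots(stack, "bassoon", dp),
                            cfg$detection$volume_bounds)$kept
    outputs$spots <- write_stage_csv(bind_rows(ribeye, bassoon),
                                     file.path(cfg$out_dir, "spots.csv"),
                                     seed, "segment")
  }

  if (isTRUE(st$classify) && !is.null(ribeye)) {
    paired <- classify_by_proximity(ribeye, bassoon, cfg$thresholds$pairing)
    outputs$classified <- write_stage_csv(paired,
                                          file.path(cfg$out_dir, "classified.csv"),
                                          seed, "classify")
    if (sum(paired$colocalized) >= 3) {
      vc <- volume_correlation(paired, bassoon)
      outputs$volume_correlation <- write_stage_csv(
        vc, file.path(cfg$out_dir, "volume_correlation.csv"), seed, "classify")
    }
  }

  if (isTRUE(st$coloc)) {
    geom <- build_cell_geometry(stack, "membrane")
    zi <- geom$central_planes[ceiling(length(geom$central_planes) / 2)]
    ring2d <- geom$ring[, , zi]
    a2 <- get_channel(stack, "ribeye")[, , zi]
    b2 <- get_channel(stack, "bassoon")[, , zi]
    ct <- costes_test(a2, b2, ring2d, n = cfg$costes$reps,
                      block_px = cfg$costes$block_px, seed = seed + 21L)
    md <- manders(a2, b2, ring2d)
    pr <- bind_rows(peripheral_ratio(stack, "ribeye", geom) |> mutate(channel = "ribeye"),
                    peripheral_ratio(stack, "bassoon", geom) |> mutate(channel = "bassoon"))
    coloc_tb <- dplyr::bind_cols(ct, md) |>
      mutate(peripheral_ratio_ribeye = pr$ratio[pr$channel == "ribeye"],
             peripheral_ratio_bassoon = pr$ratio[pr$channel == "bassoon"])
    outputs$coloc <- write_stage_csv(coloc_tb, file.path(cfg$out_dir, "coloc.csv"),
                                     seed, "coloc")
  }

  if (isTRUE(st$calcium)) {
    pr <- do.call(stimulus_protocol, cfg$protocol)
    mid_z <- sc$cell_center[["z"]]
    near <- sim$truth |>
      filter(.data$channel == "ribeye", abs(.data$z - mid_z) < 1)
    centers_with <- near |> dplyr::slice_head(n = 2)
    if (nrow(centers_with) == 0)
      centers_with <- sim$truth |> filter(.data$channel == "ribeye") |> dplyr::slice_head(n = 2)
    tr_truth <- transient_table(
      x = centers_with$x, y = centers_with$y, F0 = 100,
      amplitude = 40, onset_frame = pr$onset_frame,
      duration_frames = pr$duration_frames, decay_tau = 2)
    ser <- generate_timeseries(sc, tr_truth, n_frames = pr$onset_frame +
                                 pr$duration_frames + 10, diffuse_amplitude = 10)
    ts <- ser$series
    rois <- bind_rows(
      tibble(x = centers_with$x, y = centers_with$y),
      tibble(x = sc$cell_center[["x"]] + c(-1.5, 1.5), y = sc$cell_center[["y"]]))
    rois <- assign_roi_classes(rois, tibble(x = centers_with$x, y = centers_with$y,
                                            r = centers_with$rx))
    traces <- purrr::map_dfr(seq_len(nrow(rois)), function(i)
      roi_trace(ts, c(x = rois$x[i], y = rois$y[i]), protocol = pr))
    traces$class <- rois$class
    traces$dfmax <- vapply(seq_len(nrow(traces)), function(i)
      dFmax_over_F0(traces[i, ], pr)$value, numeric(1))
    outputs$calcium <- write_stage_csv(traces, file.path(cfg$out_dir, "calcium_rois.csv"),
                                       seed, "calcium")
  }

  if (isTRUE(st$ephys)) {
    rec <- generate_iv_recording(seed = seed + 31L)
    rec <- correct_ljp(rec)
    rec <- leak_correct_p10(rec)
    iv <- extract_iv(rec)
    qc <- qc_filter(rec, iv)
    fit <- fit_activation(iv)
    iv_out <- iv |> mutate(qc_pass = qc$pass)
    outputs$iv <- write_stage_csv(iv_out, file.path(cfg$out_dir, "iv_curve.csv"),
                                  seed, "ephys")
    outputs$activation <- write_stage_csv(tidy(fit),
                                          file.path(cfg$out_dir, "activation_fit.csv"),
                                          seed, "ephys")
  }

  if (isTRUE(st$stats) && !is.null(outputs$spots)) {
    vols <- bind_rows(ribeye |> mutate(group = "ribeye"),
                      bassoon |> mutate(group = "bassoon"))
    if (min(table(vols$group)) >= 3) {
      gt <- compare_two_groups(vols$volume[vols$group == "ribeye"],
                               vols$volume[vols$group == "bassoon"])
      outputs$stats <- write_stage_csv(glance(gt),
                                       file.path(cfg$out_dir, "stats_volume.csv"),
                                       seed, "stats")
    }
  }

  manifest <- list(
    seed = seed,
    created = "run",  # deterministic manifests: no wall-clock stamp
    package_version = as.character(utils::packageVersion("ribbonquant")),
    parameter_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    outputs = lapply(outputs, basename))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Assemble figure panels from a pipeline run directory
#'
#' Builds the standard panels (volume histogram and box plot, dF/F trace
#' overlay, IV curve) from the stage CSVs of [run_pipeline()]. Panels whose
#' inputs are missing or empty are omitted with a warning.
#'
#' @param out_dir a pipeline output directory.
#' @return named list of ggplot objects.
#' @export
make_figure_panels <- function(out_dir) {
  read_stage <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p, comment.char = "#")
  }
  panels <- list()
  spots <- read_stage("spots.csv")
  if (!is.null(spots) && nrow(spots)) {
    panels$volumes_hist <- plot_volume_histogram(spots)
    panels$volumes_box <- plot_box_summary(spots, "volume", "channel")
  } else warn("no spots: volume panels omitted")
  calc <- read_stage("calcium_rois.csv")
  if (!is.null(calc) && nrow(calc) && length(unique(calc$class)) == 2) {
    panels$dfmax_box <- plot_box_summary(calc, "dfmax", "class")
  } else warn("calcium ROI groups incomplete: dfmax panel omitted")
  iv <- read_stage("iv_curve.csv")
  if (!is.null(iv) && nrow(iv)) {
    ivc <- tibble::as_tibble(iv)
    class(ivc) <- c("iv_curve", class(ivc))
    panels$iv <- autoplot.iv_curve(ivc)
  } else warn("no IV curve: panel omitted")
  panels
}
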