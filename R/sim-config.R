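#' Configuration for the synthetic imaging generator
#'
#' Describes the virtual acquisition: voxel size (defaults mirror a confocal
#' setup with 80 x 80 nm pixels in xy and 200 nm z steps), stack shape, an
#' ellipsoidal cell with a membrane shell, the Gaussian point-spread
#' function, and a Poisson + Gaussian noise model.
#'
#' @param voxel_size named `c(x, y, z)` voxel edge lengths in µm.
#' @param stack_shape named `c(y, x, z)` stack size in voxels.
#' @param cell_semiaxes named `c(x, y, z)` ellipsoid semi-axes in µm.
#' @param cell_center named `c(x, y, z)` centre in µm; default = stack centre.
#' @param membrane_thickness thickness of the rendered membrane shell, µm.
#' @param psf_sigma named `c(x, y, z)` Gaussian PSF sigma in µm.
#' @param gain photon gain of the Poisson shot-noise stage; `NULL` disables
#'   shot noise.
#' @param read_sd Gaussian read-noise SD (intensity units); 0 disables.
#' @param membrane_intensity intensity of the membrane shell channel.
#' @param seed integer seed; fixing it makes every generator deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(voxel_size = c(x = 0.08, y = 0.08, z = 0.2),
                       stack_shape = c(y = 96, x = 96, z = 24),
                       cell_semiaxes = c(x = 3.2, y = 3.2, z = 2.0),
                       cell_center = NULL,
                       membrane_thickness = 0.16,
                       psf_sigma = c(x = 0.1, y = 0.1, z = 0.25),
                       gain = 2,
                       read_sd = 2,
                       membrane_intensity = 60,
                       seed = 1L) {
  vs <- voxel_size[c("x", "y", "z")]
  ss <- stack_shape[c("y", "x", "z")]
  if (any(vs <= 0) || membrane_thickness <= 0 || any(psf_sigma < 0))
    abort("all physical lengths must be positive")
  if (is.null(cell_center))
    cell_center <- c(x = ss[["x"]] * vs[["x"]] / 2,
                     y = ss[["y"]] * vs[["y"]] / 2,
                     z = ss[["z"]] * vs[["z"]] / 2)
  structure(list(voxel_size = vs, stack_shape = ss,
                 cell_semiaxes = cell_semiaxes[c("x", "y", "z")],
                 cell_center = cell_center[c("x", "y", "z")],
                 membrane_thickness = membrane_thickness,
                 psf_sigma = psf_sigma[c("x", "y", "z")],
                 gain = gain, read_sd = read_sd,
                 membrane_intensity = membrane_intensity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run code with a local RNG state seeded at `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
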