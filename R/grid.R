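#' Camera/detector grid description
#'
#' Geometry and acquisition metadata of the CMOS detector recording the
#' specklegrams. `tip_to_camera` (mm) and `exposure` (ms) are carried as
#' metadata only; free-space propagation from the fiber tip to the detector
#' is not modeled.
#'
#' @param width,height pixel counts of the rendered grid.
#' @param pixel_pitch pixel pitch in micrometers.
#' @param tip_to_camera fiber-tip-to-detector distance in mm (metadata).
#' @param exposure exposure time in ms (metadata).
#' @return an object of class `simulation_grid`.
#' @export
simulation_grid <- function(width = 1280L, height = 1024L, pixel_pitch = 5.3,
                            tip_to_camera = 5, exposure = 6) {
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L || height <= 0L) {
    stop_with("config", "grid dimensions must be positive (got %d x %d)",
              width, height)
  }
  if (pixel_pitch <= 0) stop_with("config", "pixel_pitch must be positive")
  structure(
    list(width = width, height = height, pixel_pitch = pixel_pitch,
         tip_to_camera = tip_to_camera, exposure = exposure),
    class = "simulation_grid"
  )
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("<simulation_grid> %d x %d px, pitch %.2f um\n",
              x$width, x$height, x$pixel_pitch))
  invisible(x)
}

#' Detector noise/quantization model
#'
#' @param bit_depth output bit depth (1..16); intensities are quantized to
#'   `2^bit_depth` levels.
#' @param shot_noise logical; apply scaled-Poisson photon shot noise.
#' @param read_noise_sd additive Gaussian read noise, in digital numbers.
#' @param full_scale_electrons photoelectron count corresponding to digital
#'   full scale; sets the relative strength of shot noise.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(bit_depth = 16L, shot_noise = TRUE,
                         read_noise_sd = 0, full_scale_electrons = 20000) {
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 16L) {
    stop_with("config", "bit_depth must be in [1, 16] (got %d)", bit_depth)
  }
  if (read_noise_sd < 0) stop_with("config", "read_noise_sd must be >= 0")
  if (full_scale_electrons <= 0) {
    stop_with("config", "full_scale_electrons must be positive")
  }
  structure(
    list(bit_depth = bit_depth, shot_noise = isTRUE(shot_noise),
         read_noise_sd = read_noise_sd,
         full_scale_electrons = full_scale_electrons),
    class = "camera_model"
  )
}
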