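#' Apply detector noise and quantization to a speckle image
#'
#' The input image is assumed to be on the detector's digital-number scale
#' (full scale `2^bit_depth - 1`). In order: scaled-Poisson shot noise
#' (intensities are converted to photoelectrons via `full_scale_electrons`,
#' Poisson-sampled, and converted back), additive Gaussian read noise,
#' clipping to `[0, 2^bit_depth - 1]`, and quantization to integer levels.
#' With both noise sources disabled the operation is the identity on images
#' that are already quantized. Deterministic given `seed`.
#'
#' @param img a [speckle_image()] on the digital-number scale.
#' @param cam a [camera_model()].
#' @param seed integer seed.
#' @return a quantized `speckle_image`.
#' @export
add_camera_noise <- function(img, cam, seed = 1L) {
  full <- 2^cam$bit_depth - 1
  x <- img$intensity
  with_seed(seed, {
    if (cam$shot_noise) {
      e <- pmax(x, 0) / full * cam$full_scale_electrons
      e <- stats::rpois(length(e), as.vector(e))
      x <- matrix(e / cam$full_scale_electrons * full, nrow(x), ncol(x))
    }
    if (cam$read_noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, cam$read_noise_sd),
                      nrow(x), ncol(x))
    }
  })
  x <- round(pmin(pmax(x, 0), full))
  speckle_image(x, concentration = img$concentration, seed = seed,
                stage_tag = img$stage_tag)
}
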