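#' Write a specklegram as 16-bit grayscale TIFF
#'
#' Intensities on the digital-number scale are mapped to `[0, 1]` by the
#' full-scale value `2^bit_depth - 1` and stored losslessly (uncompressed,
#' 16 bits per sample), so files are bit-identical across runs.
#'
#' @param intensity numeric matrix of digital numbers.
#' @param path output path.
#' @param bit_depth source bit depth.
#' @return `path`, invisibly.
#' @export
write_specklegram <- function(intensity, path, bit_depth = 16L) {
  full <- 2^bit_depth - 1
  tiff::writeTIFF(intensity / full, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a specklegram raster image
#'
#' Reads TIFF (native integer digital numbers). Multi-channel images are
#' returned as `height x width x channels` arrays for [to_grayscale()].
#'
#' @param path image path.
#' @return numeric matrix (or array) of digital numbers.
#' @export
read_specklegram <- function(path) {
  if (!file.exists(path)) stop_with("io", "no such image: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "double"
  img
}

#' Collapse a raster image to a single channel
#'
#' Single-channel inputs pass through unchanged; 3-channel inputs are
#' reduced by the unweighted channel mean.
#'
#' @param img matrix (single channel) or `H x W x 3` array.
#' @return numeric matrix.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 1L) return(array(img[, , 1], dim = dim(img)[1:2]))
    if (nc == 3L) {
      return(array((img[, , 1] + img[, , 2] + img[, , 3]) / 3,
                   dim = dim(img)[1:2]))
    }
  }
  stop_with("format", "unsupported channel count for grayscale conversion")
}

#' Normalize an image to the unit range
#'
#' `"fixed"` (default) divides by the full-scale value `2^bit_depth - 1`,
#' preserving relative brightness across frames; `"minmax"` maps the image's
#' own range onto `[0, 1]` and errors on constant images.
#'
#' @param img single-channel numeric matrix.
#' @param mode `"fixed"` or `"minmax"`.
#' @param bit_depth bit depth for fixed-scale normalization.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_unit <- function(img, mode = c("fixed", "minmax"), bit_depth = 16L) {
  mode <- match.arg(mode)
  if (!length(img)) stop_with("format", "empty image")
  if (mode == "fixed") {
    out <- img / (2^bit_depth - 1)
    if (any(out < 0) || any(out > 1)) {
      stop_with("range", "intensities exceed the stated bit depth")
    }
    out
  } else {
    rng <- range(img)
    if (rng[1] == rng[2]) {
      stop_with("zero-range", "min-max normalization undefined on a constant image")
    }
    (img - rng[1]) / (rng[2] - rng[1])
  }
}

#' Downsample an image by non-overlapping block means
#'
#' Reduces each `factor x factor` block to its arithmetic mean (1280 x 1024
#' becomes 320 x 256 at the default factor 4). The global mean intensity is
#' preserved exactly; dimensions must be divisible by `factor`.
#'
#' @param img numeric matrix.
#' @param factor integer block size; `1` is the identity.
#' @return downsampled matrix.
#' @export
downsample <- function(img, factor = 4L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop_with("config", "downsample factor must be >= 1")
  if (factor == 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  if (h %% factor != 0L || w %% factor != 0L) {
    stop_with("shape", "image %d x %d not divisible by factor %d", h, w, factor)
  }
  oh <- h %/% factor; ow <- w %/% factor
  dim(img) <- c(factor, oh, factor, ow)
  out <- colMeans(aperm(img, c(1, 3, 2, 4)), dims = 2)
  matrix(out, oh, ow)
}

#' Full preprocessing chain
#'
#' Grayscale conversion, unit-range normalization, block-mean downsampling —
#' in that order. A pure function of the input image and options.
#'
#' @param img raster image (matrix or 3-channel array) of digital numbers.
#' @param factor downsampling block size.
#' @param norm normalization mode, see [normalize_unit()].
#' @param bit_depth bit depth for fixed-scale normalization.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
preprocess_image <- function(img, factor = 4L, norm = "fixed",
                             bit_depth = 16L) {
  downsample(normalize_unit(to_grayscale(img), mode = norm,
                            bit_depth = bit_depth),
             factor = factor)
}
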