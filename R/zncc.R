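#' Zero-mean normalized cross-correlation of two images
#'
#' `zncc = sum((I0 - mean(I0)) * (I - mean(I))) /
#'  sqrt(sum((I0 - mean(I0))^2) * sum((I - mean(I))^2))`
#' over all pixels. Both images are centered by their own means and
#' normalized by their centered energies, so the statistic is symmetric,
#' bounded in `[-1, 1]` (Cauchy-Schwarz), and invariant to positive affine
#' brightness changes of either image — the property that makes it robust to
#' source-power and exposure drift between frames.
#'
#' @param reference,probe numeric matrices of identical shape, each with
#'   nonzero variance.
#' @return a single numeric correlation in `[-1, 1]`.
#' @export
zncc <- function(reference, probe) {
  if (!identical(dim(reference), dim(probe))) {
    stop_with("dimension", "images have different shapes (%s vs %s)",
              paste(dim(reference), collapse = "x"),
              paste(dim(probe), collapse = "x"))
  }
  a <- reference - mean(reference)
  b <- probe - mean(probe)
  ea <- sum(a * a); eb <- sum(b * b)
  if (ea == 0 || eb == 0) {
    stop_with("undefined-correlation",
              "ZNCC undefined for a zero-variance image")
  }
  sum(a * b) / sqrt(ea * eb)
}

#' Per-concentration ZNCC statistics against a fixed reference
#'
#' Correlates every probe image with the reference frame and aggregates the
#' values by concentration label: mean, standard deviation and count per
#' class, ordered by increasing concentration.
#'
#' @param reference preprocessed reference image (matrix).
#' @param manifest data.frame with columns `id`, `concentration_ng_per_ml`
#'   and either in-memory images supplied via `images` or readable `path`s.
#' @param images optional named list of preprocessed probe matrices keyed by
#'   manifest `id`.
#' @param preprocess optional function applied to each image (and already
#'   applied by the caller to `reference`); default identity.
#' @return a data.frame of class `correlation_curve` with columns
#'   `concentration_ng_per_ml`, `mean_zncc`, `sd_zncc`, `n`.
#' @export
correlation_curve <- function(reference, manifest, images = NULL,
                              preprocess = identity) {
  if (!nrow(manifest)) stop_with("missing-class", "empty manifest")
  vals <- vapply(seq_len(nrow(manifest)), function(i) {
    img <- if (!is.null(images)) {
      images[[manifest$id[i]]]
    } else {
      read_specklegram(manifest$path[i])
    }
    if (is.null(img)) {
      stop_with("missing-class", "no image for id %s", manifest$id[i])
    }
    zncc(reference, preprocess(img))
  }, numeric(1))
  groups <- split(vals, manifest$concentration_ng_per_ml)
  conc <- as.numeric(names(groups))
  ord <- order(conc)
  out <- data.frame(
    concentration_ng_per_ml = conc[ord],
    mean_zncc = vapply(groups, mean, numeric(1))[ord],
    sd_zncc = vapply(groups, stats::sd, numeric(1))[ord],
    n = vapply(groups, length, integer(1))[ord],
    row.names = NULL
  )
  class(out) <- c("correlation_curve", "data.frame")
  out
}
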