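#' Build an orthonormal surrogate basis of transverse mode profiles
#'
#' The guided modes of the tapered multimode fiber are represented by smooth
#' surrogate profiles that are orthonormal over the rendering grid. The
#' default `"smooth"` type draws seeded random coefficients over a low-order
#' 2D cosine-product dictionary (low spatial frequencies dominate) and
#' orthonormalizes the resulting fields with a QR sweep; `"cosine"` uses the
#' first `M` cosine products directly. Either choice preserves the
#' interference statistics that the modal superposition needs without
#' solving an electromagnetic eigenproblem.
#'
#' @param M number of modes (>= 1).
#' @param grid a [simulation_grid()].
#' @param seed integer seed; the basis is deterministic given `seed`.
#' @param type `"smooth"` (seeded random smooth fields) or `"cosine"`.
#' @return an object of class `mode_basis`: a `(width*height) x M` matrix of
#'   orthonormal profiles plus grid dimensions.
#' @export
build_mode_basis <- function(M, grid, seed = 1L, type = c("smooth", "cosine")) {
  type <- match.arg(type)
  M <- as.integer(M)
  if (M < 1L) stop_with("config", "M must be >= 1")
  npix <- grid$width * grid$height
  if (M > npix) {
    stop_with("infeasible-basis",
              "cannot build %d orthonormal profiles on a %d-pixel grid",
              M, npix)
  }
  H <- grid$height; W <- grid$width
  # cosine dictionary: f_{kx,ky}(x,y) = cos(pi kx (x+.5)/W) cos(pi ky (y+.5)/H)
  kmax <- ceiling(sqrt(M)) + 2L
  freqs <- expand.grid(kx = 0:(kmax - 1L), ky = 0:(kmax - 1L))
  nfeat <- nrow(freqs)
  cy <- outer(seq_len(H) - 0.5, freqs$ky, function(y, k) cos(pi * k * y / H))
  cx <- outer(seq_len(W) - 0.5, freqs$kx, function(x, k) cos(pi * k * x / W))
  if (type == "smooth") {
    coef <- with_seed(seed, {
      decay <- 1 / (1 + freqs$kx + freqs$ky)
      matrix(stats::rnorm(nfeat * M), nfeat, M) * decay
    })
  } else {
    ord <- order(freqs$kx + freqs$ky, freqs$kx)
    coef <- matrix(0, nfeat, M)
    coef[cbind(ord[seq_len(M)], seq_len(M))] <- 1
  }
  profiles <- matrix(0, npix, M)
  for (f in seq_len(nfeat)) {
    if (all(coef[f, ] == 0)) next
    feat <- as.vector(cy[, f] %o% cx[, f])  # column-major H x W
    profiles <- profiles + feat %o% coef[f, ]
  }
  q <- qr.Q(qr(profiles))[, seq_len(M), drop = FALSE]
  structure(
    list(profiles = q, width = W, height = H, M = M, type = type, seed = seed),
    class = "mode_basis"
  )
}

#' Gram matrix of a mode basis
#'
#' Pairwise discrete inner products of the profiles; identity when the basis
#' is orthonormal.
#'
#' @param basis a `mode_basis`.
#' @return an `M x M` matrix.
#' @export
basis_gram <- function(basis) {
  crossprod(basis$profiles)
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("<mode_basis> %d %s profiles on %d x %d grid (seed %d)\n",
              x$M, x$type, x$width, x$height, x$seed))
  invisible(x)
}
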