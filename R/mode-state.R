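#' Guided-mode ensemble state
#'
#' Holds per-mode powers `p_m` and phases `phi_m` of the `M` guided modes.
#' Powers are normalized to sum to 1; amplitudes are `sqrt(p_m)`.
#'
#' @param powers non-negative numeric vector of mode powers (renormalized).
#' @param phases numeric vector of mode phases in radians, same length.
#' @return an object of class `mode_state`.
#' @export
mode_state <- function(powers, phases) {
  if (length(powers) != length(phases)) {
    stop_with("dimension", "powers and phases must have equal length")
  }
  if (any(!is.finite(powers)) || any(powers < 0)) {
    stop_with("invariant", "mode powers must be finite and non-negative")
  }
  tot <- sum(powers)
  if (tot <= 0) stop_with("invariant", "total mode power must be positive")
  structure(
    list(M = length(powers), powers = powers / tot, phases = phases),
    class = "mode_state"
  )
}

#' Seeded random baseline mode state
#'
#' Draws powers uniformly on (0.5, 1.5) before normalization and phases
#' uniformly on `[0, 2*pi)`, the baseline excitation of the fiber before any
#' analyte exposure.
#'
#' @param M mode count.
#' @param seed integer seed.
#' @return a `mode_state`.
#' @export
random_mode_state <- function(M, seed = 1L) {
  with_seed(seed, {
    mode_state(stats::runif(M, 0.5, 1.5), stats::runif(M, 0, 2 * pi))
  })
}

#' @export
print.mode_state <- function(x, ...) {
  cat(sprintf("<mode_state> M = %d, sum(p) = %.6f\n", x$M, sum(x$powers)))
  invisible(x)
}

mode_amplitudes <- function(state) sqrt(state$powers)

#' Symmetric mode-coupling matrix
#'
#' Entries `h[m, n]` are non-negative coupling coefficients governing power
#' exchange between modes `m` and `n` under an external refractive-index
#' perturbation; the matrix is symmetric with zero diagonal.
#'
#' @param M mode count.
#' @param h_scale entries are drawn i.i.d. uniform on `[0, h_scale]` before
#'   symmetrization.
#' @param seed integer seed.
#' @return an `M x M` matrix of class `coupling_matrix`.
#' @export
coupling_matrix <- function(M, h_scale = 0.05, seed = 1L) {
  h <- with_seed(seed, matrix(stats::runif(M * M, 0, h_scale), M, M))
  h <- (h + t(h)) / 2
  diag(h) <- 0
  structure(h, class = c("coupling_matrix", "matrix", "array"))
}

validate_coupling <- function(h) {
  if (!is.matrix(h) || nrow(h) != ncol(h)) {
    stop_with("invariant", "coupling matrix must be square")
  }
  if (any(h < 0)) stop_with("invariant", "coupling coefficients must be >= 0")
  if (any(abs(h - t(h)) > 1e-12)) {
    stop_with("invariant", "coupling matrix must be symmetric")
  }
  if (any(diag(h) != 0)) {
    stop_with("invariant", "coupling matrix diagonal must be zero")
  }
  invisible(h)
}

#' Power increments from inter-mode coupling
#'
#' One step of power exchange between guided modes under an external
#' perturbation. Under the default `"relax"` convention the increment for
#' mode m is `gain * sum_{n != m} h[m,n] * (p_n - p_m)`, which moves power
#' toward equipartition; `"amplify"` uses the opposite sign `(p_m - p_n)`.
#' Total power is conserved under either convention (the summand is
#' antisymmetric against the symmetric coupling matrix), so
#' `sum(couple_powers(...)) == 0` up to float tolerance.
#'
#' @param state a [mode_state()].
#' @param h a [coupling_matrix()] (or any symmetric non-negative matrix with
#'   zero diagonal).
#' @param gain non-negative step scale.
#' @param convention `"relax"` (default) or `"amplify"`.
#' @return numeric vector of `M` power increments summing to zero.
#' @export
couple_powers <- function(state, h, gain = 1,
                          convention = c("relax", "amplify")) {
  convention <- match.arg(convention)
  validate_coupling(h)
  if (nrow(h) != state$M) {
    stop_with("dimension", "coupling matrix size %d does not match M = %d",
              nrow(h), state$M)
  }
  if (gain < 0) stop_with("config", "gain must be >= 0")
  p <- state$powers
  dp <- gain * (as.vector(h %*% p) - p * rowSums(h))  # relax: sum h (p_n - p_m)
  if (convention == "amplify") dp <- -dp
  dp
}

#' Superpose the modal fields into the output-face complex field
#'
#' Computes `A(x, y) = sum_m a_m * psi_m(x, y) * exp(1i * phi_m)`, the
#' coherent superposition of the guided modes at the fiber output face.
#'
#' @param state a [mode_state()].
#' @param basis a [build_mode_basis()] result with matching `M`.
#' @return a complex `height x width` matrix.
#' @export
synthesize_field <- function(state, basis) {
  if (state$M != basis$M) {
    stop_with("dimension", "mode_state M = %d does not match basis M = %d",
              state$M, basis$M)
  }
  coef <- mode_amplitudes(state) * exp(1i * state$phases)
  field <- basis$profiles %*% coef
  matrix(field, nrow = basis$height, ncol = basis$width)
}

#' Convert a complex field to a speckle intensity image
#'
#' `I(x, y) = |A(x, y)|^2`, equivalently the double sum over mode pairs
#' `sum_m sum_n a_m a_n psi_m psi_n exp(1i (phi_m - phi_n))`.
#'
#' @param field complex matrix from [synthesize_field()].
#' @param concentration optional ng/mL label.
#' @param seed optional seed metadata.
#' @param stage_tag free-text tag.
#' @return an object of class `speckle_image`.
#' @export
field_to_intensity <- function(field, concentration = NA_real_,
                               seed = NA_integer_, stage_tag = "") {
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field)))) {
    stop_with("propagation", "field contains non-finite values")
  }
  speckle_image(Mod(field)^2, concentration = concentration, seed = seed,
                stage_tag = stage_tag)
}

#' Speckle intensity image container
#'
#' @param intensity non-negative numeric matrix `I(x, y)`.
#' @param concentration ng/mL label (NA for reference frames).
#' @param seed integer seed metadata.
#' @param stage_tag free text.
#' @return an object of class `speckle_image`.
#' @export
speckle_image <- function(intensity, concentration = NA_real_,
                          seed = NA_integer_, stage_tag = "") {
  if (!is.matrix(intensity)) stop_with("invariant", "intensity must be a matrix")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_with("invariant", "intensities must be finite and non-negative")
  }
  structure(
    list(intensity = intensity, concentration = concentration,
         seed = seed, stage_tag = stage_tag),
    class = "speckle_image"
  )
}

#' @export
print.speckle_image <- function(x, ...) {
  cat(sprintf("<speckle_image> %d x %d, concentration = %s ng/mL%s\n",
              nrow(x$intensity), ncol(x$intensity),
              format(x$concentration),
              if (nzchar(x$stage_tag)) paste0(" [", x$stage_tag, "]") else ""))
  invisible(x)
}
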