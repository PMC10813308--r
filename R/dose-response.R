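#' Concentration-to-perturbation dose-response model
#'
#' Maps an analyte concentration (ng/mL) to a dimensionless perturbation
#' strength through a saturating Hill curve,
#' `r(c) = response_max * c^h / (K^h + c^h)`, the standard functional form
#' for receptor-binding dose response. The perturbation drives per-mode phase
#' shifts `beta_m * r(c)` and one power-coupling step of gain
#' `coupling_scale * r(c)`, emulating the refractive-index change that
#' antigen binding induces at the taper surface. `r(0) = 0`, `r` is strictly
#' increasing for `hill_h > 0` and bounded by `response_max`.
#'
#' @param response_max maximum perturbation strength (dimensionless).
#' @param half_sat_K half-saturation concentration in ng/mL.
#' @param hill_h Hill exponent (> 0).
#' @param mode_sensitivities numeric vector `beta_m` (radians per unit
#'   response), one per mode; drawn by [draw_mode_sensitivities()] when the
#'   model is built from a config.
#' @param coupling_scale gain applied to the power-coupling step per unit
#'   response.
#' @return an object of class `dose_response_model`.
#' @export
dose_response_model <- function(response_max, half_sat_K = 100, hill_h = 1,
                                mode_sensitivities = numeric(),
                                coupling_scale = 1) {
  if (response_max < 0) stop_with("config", "response_max must be >= 0")
  if (half_sat_K <= 0) stop_with("config", "half_sat_K must be positive")
  if (hill_h <= 0) stop_with("config", "hill_h must be positive")
  structure(
    list(response_max = response_max, half_sat_K = half_sat_K,
         hill_h = hill_h, mode_sensitivities = mode_sensitivities,
         coupling_scale = coupling_scale),
    class = "dose_response_model"
  )
}

#' Seeded per-mode phase sensitivities
#'
#' Draws `beta_m ~ Uniform(-beta_range, beta_range)`, the per-mode phase
#' shift (radians) per unit dose response.
#'
#' @param M mode count.
#' @param beta_range half-width of the uniform range, radians.
#' @param seed integer seed.
#' @return numeric vector of length `M`.
#' @export
draw_mode_sensitivities <- function(M, beta_range = 1.5, seed = 1L) {
  with_seed(seed, stats::runif(M, -beta_range, beta_range))
}

#' Evaluate the dose response r(c)
#'
#' @param model a [dose_response_model()].
#' @param c concentration(s) in ng/mL, `>= 0`.
#' @return perturbation strength(s) in `[0, response_max)`.
#' @export
dose_response <- function(model, c) {
  if (any(c < 0)) stop_with("domain", "concentration must be >= 0")
  h <- model$hill_h
  ch <- c^h
  out <- model$response_max * ch / (model$half_sat_K^h + ch)
  out[c == 0] <- 0
  out
}

#' Perturb a mode state according to an analyte concentration
#'
#' Applies the dose response `r(c)`: phases shift by `beta_m * r(c)` and, if
#' a coupling matrix is supplied, powers take one [couple_powers()] step with
#' gain `coupling_scale * r(c)`, are clipped at zero and renormalized to
#' sum 1. At `c = 0` the input state is returned unchanged.
#'
#' @param state a [mode_state()].
#' @param dose a [dose_response_model()] whose `mode_sensitivities` length
#'   matches `state$M`.
#' @param c concentration in ng/mL (scalar, `>= 0`).
#' @param coupling optional [coupling_matrix()] enabling the power-exchange
#'   step.
#' @param convention coupling sign convention, see [couple_powers()].
#' @return a new `mode_state`.
#' @export
apply_concentration <- function(state, dose, c, coupling = NULL,
                                convention = "relax") {
  if (length(c) != 1L || c < 0) {
    stop_with("domain", "concentration must be a single value >= 0")
  }
  if (length(dose$mode_sensitivities) != state$M) {
    stop_with("dimension",
              "dose model has %d mode sensitivities for M = %d modes",
              length(dose$mode_sensitivities), state$M)
  }
  r <- dose_response(dose, c)
  if (r == 0) return(state)
  phases <- state$phases + dose$mode_sensitivities * r
  powers <- state$powers
  if (!is.null(coupling)) {
    dp <- couple_powers(state, coupling, gain = dose$coupling_scale * r,
                        convention = convention)
    powers <- pmax(powers + dp, 0)
  }
  mode_state(powers, phases)
}
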