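#' Weakly compressible state equation (Tait/Cole form)
#'
#' WCSPH closes the continuity/momentum system with a stiff barotropic
#' equation of state instead of a pressure solve:
#' `p = (c0^2 rho0 / gamma) ((rho/rho0)^gamma - 1)`.
#' Choosing the numerical speed of sound `c0` at least ten times the expected
#' peak fluid speed keeps relative density fluctuations below about 1%.
#'
#' @param rho0 Reference density (kg/m^3).
#' @param c0 Numerical speed of sound (m/s).
#' @param gamma Polytropic exponent (default 7, standard for liquids).
#' @return An object of class `state_equation`.
#' @export
state_equation <- function(rho0 = 1060, c0, gamma = 7) {
  stopifnot(rho0 > 0, c0 > 0, gamma >= 1)
  structure(list(rho0 = rho0, c0 = c0, gamma = gamma),
            class = "state_equation")
}

#' Pressure from density
#'
#' @param rho Density (kg/m^3), positive; vectorised.
#' @param eos A [state_equation()].
#' @return Pressure (Pa); zero at `rho = rho0`, strictly increasing in `rho`.
#' @export
equation_of_state <- function(rho, eos) {
  stopifnot(inherits(eos, "state_equation"))
  if (any(rho <= 0)) stop("invalid density: rho must be positive", call. = FALSE)
  B <- eos$c0^2 * eos$rho0 / eos$gamma
  B * ((rho / eos$rho0)^eos$gamma - 1)
}

#' Clinical pressure unit conversion
#'
#' Haemodynamic pressures are reported clinically in mmHg;
#' 1 mmHg = 133.322 Pa.
#'
#' @param p Pressure(s) in Pa (for `pa_to_mmhg`) or mmHg (for
#'   `mmhg_to_pa`).
#' @return Converted pressure(s).
#' @export
pa_to_mmhg <- function(p) p / 133.322

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(p) p * 133.322

#' Recommended speed of sound for a target peak speed
#'
#' `c0 = 10 * max(U_peak, sqrt(g * H))`, the usual WCSPH weak-compressibility
#' design rule (density fluctuation of order `(U/c0)^2` ~ 1%).
#'
#' @param u_peak Expected peak fluid speed (m/s).
#' @param g Body-force magnitude (m/s^2), optional.
#' @param height Characteristic height for the hydrostatic head (m), optional.
#' @return Speed of sound (m/s).
#' @export
design_sound_speed <- function(u_peak, g = 0, height = 0) {
  10 * max(u_peak, sqrt(abs(g) * height))
}
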