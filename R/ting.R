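#' Hertz force for a rigid sphere on an elastic half-space
#'
#' \eqn{F = \frac{4}{3}\frac{E}{1-\nu^2}\,\delta^{3/2}\sqrt{R}} for a
#' spherical tip of radius R indenting an incompressible soft half-space to
#' depth \eqn{\delta}.
#'
#' @param depth Indentation depth (m), vectorised; negative values give 0.
#' @param E Young's modulus (Pa).
#' @param tip_radius Tip radius (m).
#' @param nu Poisson ratio (0.5 for incompressible soft tissue).
#' @return Force in newtons.
#' @export
hertz_force <- function(depth, E, tip_radius = 9e-6, nu = 0.5) {
  check_positive(E, "E")
  check_positive(tip_radius, "tip_radius")
  4 / 3 * E / (1 - nu^2) * pmax(depth, 0)^1.5 * sqrt(tip_radius)
}

#' Ting forward force for power-law rheology
#'
#' Computes the force history of a spherical tip on a viscoelastic half-space
#' with relaxation modulus \eqn{E(t) = E_1 t^{-\alpha}} for a single
#' load-dwell-retract depth history. While contact grows the force is the
#' hereditary convolution of the relaxation modulus with
#' \eqn{d(\delta^{3/2})/dt}; during retraction the integral is truncated at
#' the auxiliary time \eqn{t_1(t)} at which the (virtually unloaded) contact
#' radius equals the current one. The weakly singular kernel is integrated
#' analytically interval-by-interval against a piecewise-linear
#' \eqn{\delta^{3/2}}, and \eqn{t_1} is found by bracketed bisection with the
#' non-increasing property enforced.
#'
#' @param depth_history Indentation depth (m) at each sample; single-peaked
#'   (one load-dwell-retract cycle), non-negative after contact.
#' @param time Sample times (s), strictly increasing; history starts at
#'   contact.
#' @param E1 Relaxation scale factor — the relaxation modulus at t = 1 s (Pa).
#' @param alpha Power-law exponent in `[0, 1)`; 0 is elastic (Hertz).
#' @param tip_radius,nu Probe radius (m) and Poisson ratio.
#' @return Force in newtons at each sample.
#' @export
ting_forward <- function(depth_history, time, E1, alpha, tip_radius = 9e-6,
                         nu = 0.5) {
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1)")
  check_positive(E1, "E1")
  ting_force_cpp(as.numeric(time), as.numeric(depth_history), E1, alpha,
                 tip_radius, nu)
}

#' Closed-form Ting force under constant-velocity ramp loading
#'
#' For \eqn{\delta = v t} the hereditary convolution has the closed form
#' \deqn{F(t) = \frac{4\sqrt{R}}{3(1-\nu^2)} E_1 v^{3/2} \tfrac{3}{2}
#'   B(3/2, 1-\alpha)\, t^{3/2-\alpha}}
#' (B the Beta function). Serves as an independent oracle for the numerical
#' forward solver.
#'
#' @param t Times since contact (s).
#' @param v Ramp speed (m/s).
#' @inheritParams ting_forward
#' @return Force in newtons.
#' @export
ramp_force_closed_form <- function(t, v, E1, alpha, tip_radius = 9e-6,
                                   nu = 0.5) {
  pref <- 4 * sqrt(tip_radius) / (3 * (1 - nu^2))
  pref * E1 * v^1.5 * 1.5 * beta(1.5, 1 - alpha) * pmax(t, 0)^(1.5 - alpha)
}
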