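# Hydrodynamic coefficient correlations for the intermediate-Reynolds regime.
#
# All four coefficient families are parametric strategies collected in a
# `cteno_coefficients` object so alternative correlations can be swapped in
# through the configuration without touching the dynamics:
#
#  * plate drag         C_A(Re_p)  = C_inf + alpha_A / sqrt(Re_p)
#  * body drag          C_B(Re_b)  = (24 / Re_b) * K * (1 + c1 * Re_b^c2)
#  * added mass         C_m        = Lamb's potential-flow coefficients
#  * rotational torque  C_R(Re_r)  = (16 pi / Re_r) * G * (1 + c3 * Re_r^c4)
#
# The body-drag shape factors K (parallel/perpendicular) are fixed by
# requiring the Stokes limit to reproduce Oberbeck's exact creeping-flow drag
# of a translating prolate spheroid, with reference areas pi*a^2 (axial) and
# pi*a*b (lateral) and Reynolds number based on body length; the finite-Re
# correction is the Schiller-Naumann form, giving exactly the classical
# sphere correlation when a = b. The torque factors G likewise reduce to the
# exact creeping-flow rotational drag of a spheroid (8 pi mu r^3 for the
# sphere) with a square-root inertial correction.

#' Default hydrodynamic coefficient model
#'
#' Build the default set of drag, added-mass and torque coefficient
#' correlations for a prolate spheroid of semi-axes `a` (minor) and `b`
#' (major). All correlations clamp their Reynolds-number argument to the
#' stated validity band.
#'
#' @param a,b body semi-minor and semi-major axes (m).
#' @param C_inf,alpha_A plate (normal flat plate) drag parameters.
#' @param c1,c2 body-drag finite-Re correction parameters.
#' @param c3,c4 rotational-torque finite-Re correction parameters.
#' @param Re_band two-element validity band for translational Reynolds
#'   numbers; arguments outside are clamped.
#' @return object of class `cteno_coefficients`: parameters plus the derived
#'   shape factors `K_par`, `K_perp`, `Cm_par`, `Cm_perp`, `G_par`, `G_perp`.
#' @export
#' @examples
#' cf <- default_coefficients(3.05e-3, 3.9e-3)
#' cf$Cm_par < cf$Cm_perp   # prolate: axial added mass below lateral
default_coefficients <- function(a, b, C_inf = 1.95, alpha_A = 10,
                                 c1 = 0.15, c2 = 0.687,
                                 c3 = 0.2, c4 = 0.5,
                                 Re_band = c(1e-3, 1e5)) {
  stopifnot(a > 0, b >= a)
  e <- if (b > a) sqrt(1 - (a / b)^2) else 0
  L_B <- 2 * b
  if (e < 1e-8) {
    K_par <- K_perp <- b / a        # = 1 for a sphere
    Cm_par <- Cm_perp <- 0.5
    G_par <- G_perp <- 1
  } else {
    Lg <- log((1 + e) / (1 - e))
    # Oberbeck creeping-flow drag, F = mu * U * D
    D_par  <- 16 * pi * e^3 * b / ((1 + e^2) * Lg - 2 * e)
    D_perp <- 32 * pi * e^3 * b / ((3 * e^2 - 1) * Lg + 2 * e)
    K_par  <- D_par  * L_B / (12 * pi * a^2)
    K_perp <- D_perp * L_B / (12 * pi * a * b)
    # Lamb potential-flow added-mass coefficients
    alpha0 <- 2 * (1 - e^2) / e^3 * (atanh(e) - e)
    beta0  <- 1 / e^2 - (1 - e^2) / e^3 * atanh(e)
    Cm_par  <- alpha0 / (2 - alpha0)
    Cm_perp <- beta0 / (2 - beta0)
    # creeping-flow rotational drag, T = mu * omega * f
    f_par  <- 32 * pi / 3 * e^3 * a^2 * b / (2 * e - (1 - e^2) * Lg)
    f_perp <- 32 * pi / 3 * e^3 * (a^2 + b^2) * b / (-2 * e + (1 + e^2) * Lg)
    r_e <- (a^2 * b)^(1 / 3)
    G_par  <- f_par  / (8 * pi * r_e^3)
    G_perp <- f_perp / (8 * pi * r_e^3)
  }
  structure(list(a = a, b = b, e = e, L_B = L_B,
                 C_inf = C_inf, alpha_A = alpha_A,
                 c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 K_par = K_par, K_perp = K_perp,
                 Cm_par = Cm_par, Cm_perp = Cm_perp,
                 G_par = G_par, G_perp = G_perp,
                 Re_band = Re_band),
            class = "cteno_coefficients")
}

#' @export
print.cteno_coefficients <- function(x, ...) {
  cat("Hydrodynamic coefficient model (quasi-steady, intermediate Re)\n")
  cat(sprintf("  plate:      C_A = %.3g + %.3g / sqrt(Re_p)\n", x$C_inf, x$alpha_A))
  cat(sprintf("  body drag:  K_par = %.4g, K_perp = %.4g (Schiller-Naumann correction %.3g * Re^%.3g)\n",
              x$K_par, x$K_perp, x$c1, x$c2))
  cat(sprintf("  added mass: Cm_par = %.4g, Cm_perp = %.4g\n", x$Cm_par, x$Cm_perp))
  cat(sprintf("  torque:     G_par = %.4g, G_perp = %.4g (correction %.3g * Re^%.3g)\n",
              x$G_par, x$G_perp, x$c3, x$c4))
  cat(sprintf("  validity:   Re in [%g, %g] (clamped outside)\n",
              x$Re_band[1], x$Re_band[2]))
  invisible(x)
}

clamp_re <- function(Re, coeffs, warn = FALSE) {
  lo <- coeffs$Re_band[1]; hi <- coeffs$Re_band[2]
  out <- Re < lo | Re > hi
  if (warn && any(out & Re > 0))
    warning(sprintf("%d Reynolds-number value(s) outside validity band [%g, %g]; clamped",
                    sum(out & Re > 0), lo, hi))
  pmin(pmax(Re, lo), hi)
}

#' Plate drag coefficient
#'
#' Quasi-steady drag coefficient of a normal flat plate oscillating at
#' intermediate Reynolds number, evaluated at the instantaneous plate
#' Reynolds number `Re_p = |x_A_dot| * y_A / nu`.
#'
#' @param Re_p plate Reynolds number (vectorized).
#' @param coeffs a [default_coefficients()] object.
#' @return drag coefficient(s).
#' @export
plate_drag_coefficient <- function(Re_p, coeffs) {
  Re_p <- clamp_re(Re_p, coeffs, warn = TRUE)
  coeffs$C_inf + coeffs$alpha_A / sqrt(Re_p)
}

#' Body drag coefficients
#'
#' Longitudinal and lateral drag coefficients of the translating spheroid as
#' functions of the body Reynolds number `Re_b = |V| * L_B / nu`. Both
#' approach the Oberbeck creeping-flow limit as `Re_b -> 0` (the classical
#' `24/Re` for a sphere) and decrease monotonically with `Re_b`.
#'
#' @param Re_b body Reynolds number (vectorized).
#' @param coeffs a [default_coefficients()] object.
#' @return list with components `par` and `perp`.
#' @export
body_drag_coefficients <- function(Re_b, coeffs) {
  Re_b <- clamp_re(Re_b, coeffs, warn = TRUE)
  corr <- 1 + coeffs$c1 * Re_b^coeffs$c2
  list(par = 24 / Re_b * coeffs$K_par * corr,
       perp = 24 / Re_b * coeffs$K_perp * corr)
}

#' Added-mass coefficients
#'
#' Lamb's exact potential-flow added-mass coefficients of the prolate
#' spheroid; both equal 0.5 for a sphere.
#'
#' @param coeffs a [default_coefficients()] object.
#' @return list with components `par` and `perp`.
#' @export
added_mass_coefficients <- function(coeffs) {
  list(par = coeffs$Cm_par, perp = coeffs$Cm_perp)
}

#' Rotational torque coefficients
#'
#' Torque coefficients of the rotating spheroid as functions of the
#' rotational Reynolds number `Re_r = |omega| * (d_e/2)^2 / nu`, reducing to
#' the exact creeping-flow rotational drag in the `Re_r -> 0` limit.
#'
#' @param Re_r rotational Reynolds number (vectorized).
#' @param coeffs a [default_coefficients()] object.
#' @return list with components `par` (roll) and `perp` (pitch/yaw).
#' @export
rotation_torque_coefficients <- function(Re_r, coeffs) {
  Re_r <- clamp_re(Re_r, coeffs, warn = TRUE)
  corr <- 1 + coeffs$c3 * Re_r^coeffs$c4
  list(par = 16 * pi / Re_r * coeffs$G_par * corr,
       perp = 16 * pi / Re_r * coeffs$G_perp * corr)
}
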