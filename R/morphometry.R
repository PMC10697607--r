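#' Ctenophore morphometry
#'
#' Bundle the nine body/row measurements that fix the model geometry: the
#' spheroidal body dimensions, the ctene (comb plate) length, the normalized
#' inter-ctene spacing, the per-row ctene counts, the row azimuths measured
#' from the tentacular plane, and the polar position of the most aboral ctene.
#'
#' All lengths are in metres internally; the configuration reader accepts mm.
#'
#' @param L_B body length (m), aboral-oral extent.
#' @param d_B body diameter (m), measured in the tentacular plane.
#' @param l ctene length (m), the fully extended plate length.
#' @param s normalized inter-ctene spacing, arc distance between adjacent
#'   ctenes divided by the ctene length (so the arc spacing is `delta = s*l`).
#' @param n_S number of ctenes on each sagittal row.
#' @param n_T number of ctenes on each tentacular row.
#' @param eps_S sagittal row azimuth from the tentacular plane (degrees).
#' @param eps_T tentacular row azimuth from the tentacular plane (degrees).
#' @param kappa polar angle of the most aboral ctene, measured about the
#'   centroid from the aboral pole (degrees).
#' @return an object of class `cteno_morphometry` (a named list) with the
#'   fields above plus `delta = s*l` in metres.
#' @export
#' @examples
#' m <- morphometry()           # population-mean defaults
#' m$delta * 1e3                # inter-ctene arc spacing in mm
morphometry <- function(L_B = 7.8e-3, d_B = 6.1e-3, l = 0.5e-3, s = 0.8,
                        n_S = 10L, n_T = 7L, eps_S = 63.9, eps_T = 23,
                        kappa = 27) {
  stopifnot(is.finite(L_B), is.finite(d_B), is.finite(l), is.finite(s))
  if (L_B <= 0 || d_B <= 0 || l <= 0 || s <= 0)
    stop("all morphometric lengths and the spacing ratio must be positive")
  n_S <- as.integer(round(n_S)); n_T <- as.integer(round(n_T))
  if (n_S < 1L || n_T < 1L) stop("row ctene counts must be >= 1")
  if (!(eps_T > 0 && eps_S > eps_T && eps_S < 90))
    stop("row azimuths must satisfy 0 < eps_T < eps_S < 90 degrees")
  if (!(kappa > 0 && kappa < 90))
    stop("kappa must lie in (0, 90) degrees")
  m <- structure(list(L_B = L_B, d_B = d_B, l = l, s = s, delta = s * l,
                      n_S = n_S, n_T = n_T, eps_S = eps_S, eps_T = eps_T,
                      kappa = kappa),
                 class = "cteno_morphometry")
  # the meridian arc spanned by the longest row must fit on the half-meridian
  half <- meridian_arc_length(m, pi)
  u0 <- kappa_to_meridian_angle(m)
  need <- meridian_arc_length(m, u0) + (max(n_S, n_T) - 1L) * m$delta
  if (need > half)
    stop("ctene row overruns the oral pole: reduce kappa, s, or the counts")
  m
}

#' @export
print.cteno_morphometry <- function(x, ...) {
  cat("Ctenophore morphometry\n")
  cat(sprintf("  body       : L_B = %.3g mm, d_B = %.3g mm\n",
              x$L_B * 1e3, x$d_B * 1e3))
  cat(sprintf("  ctenes     : l = %.3g mm, spacing delta = %.3g mm (s = %.3g)\n",
              x$l * 1e3, x$delta * 1e3, x$s))
  cat(sprintf("  rows       : n_S = %d, n_T = %d per row (8 rows, %d ctenes)\n",
              x$n_S, x$n_T, 4L * (x$n_S + x$n_T)))
  cat(sprintf("  angles     : eps_S = %.3g deg, eps_T = %.3g deg, kappa = %.3g deg\n",
              x$eps_S, x$eps_T, x$kappa))
  invisible(x)
}

#' Fluid properties
#'
#' @param rho fluid density (kg/m^3). Default is seawater.
#' @param nu kinematic viscosity (m^2/s). Default is seawater at ~21 C.
#' @return object of class `cteno_fluid`.
#' @export
fluid_properties <- function(rho = 1025, nu = 1.05e-6) {
  if (!is.finite(rho) || !is.finite(nu) || rho <= 0 || nu <= 0)
    stop("fluid density and kinematic viscosity must be positive")
  structure(list(rho = rho, nu = nu), class = "cteno_fluid")
}

#' Spheroidal body properties
#'
#' Derive the rigid-body properties of the neutrally buoyant prolate spheroid:
#' semi-axes, volume, mass, equivalent-sphere diameter and the (diagonal)
#' moment-of-inertia matrix of a homogeneous solid spheroid in the body frame
#' (axis 1 = aboral-oral symmetry axis).
#'
#' @param morph a [morphometry()] object.
#' @param fluid a [fluid_properties()] object.
#' @return object of class `cteno_body`: list with `a` (semi-minor, m),
#'   `b` (semi-major, m), `V` (m^3), `m` (kg), `d_e` (m) and `I` (3x3 kg m^2).
#' @export
#' @examples
#' build_body(morphometry(), fluid_properties())
build_body <- function(morph, fluid = fluid_properties()) {
  stopifnot(inherits(morph, "cteno_morphometry"), inherits(fluid, "cteno_fluid"))
  a <- morph$d_B / 2
  b <- morph$L_B / 2
  V <- 4 / 3 * pi * a^2 * b
  m <- fluid$rho * V                      # neutral buoyancy
  d_e <- 2 * (a^2 * b)^(1 / 3)
  I1 <- 2 / 5 * m * a^2                   # about the symmetry axis
  I2 <- 1 / 5 * m * (a^2 + b^2)           # about any transverse axis
  structure(list(a = a, b = b, V = V, m = m, d_e = d_e,
                 I = diag(c(I1, I2, I2))),
            class = "cteno_body")
}

#' @export
print.cteno_body <- function(x, ...) {
  cat("Spheroidal body\n")
  cat(sprintf("  semi-axes a = %.4g mm, b = %.4g mm; d_e = %.4g mm\n",
              x$a * 1e3, x$b * 1e3, x$d_e * 1e3))
  cat(sprintf("  V = %.4g mm^3, m = %.4g mg\n", x$V * 1e9, x$m * 1e6))
  cat(sprintf("  I = diag(%.3e, %.3e, %.3e) kg m^2\n",
              x$I[1, 1], x$I[2, 2], x$I[3, 3]))
  invisible(x)
}
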