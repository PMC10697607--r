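#' Global-to-body rotation matrix
#'
#' Build the yaw-pitch-roll rotation matrix mapping global vectors into the
#' body frame, `x_body = R %*% x_global`. The rotation sequence is yaw (psi,
#' about the body 3-axis), pitch (theta, about the body 2-axis), then roll
#' (phi, about the body 1-axis), the convention standard in vehicle dynamics.
#'
#' @param psi,theta,phi yaw, pitch, roll (radians).
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
#' @examples
#' R <- build_rotation_matrix(pi / 2, 0, 0)
#' R %*% c(0, 1, 0)   # global e2 maps onto body e1
build_rotation_matrix <- function(psi, theta, phi) {
  if (!all(is.finite(c(psi, theta, phi))))
    stop("Euler angles must be finite")
  cps <- cos(psi); sps <- sin(psi)
  cth <- cos(theta); sth <- sin(theta)
  cph <- cos(phi); sph <- sin(phi)
  matrix(c(
    cth * cps,                    cth * sps,                   -sth,
    sph * sth * cps - cph * sps,  sph * sth * sps + cph * cps,  sph * cth,
    cph * sth * cps + sph * sps,  cph * sth * sps - sph * cps,  cph * cth
  ), nrow = 3, byrow = TRUE)
}

#' Euler-angle rates from body angular velocity
#'
#' Kinematic relation converting the body-frame angular velocity into
#' yaw/pitch/roll rates for the yaw-pitch-roll sequence used by
#' [build_rotation_matrix()]. The relation is singular at pitch = +/- 90
#' degrees (gimbal lock); a hard guard rejects `|cos(theta)| <= 1e-6` rather
#' than regularizing silently, since the modelled maneuvers are yaw/pitch
#' turns with negligible roll and never approach the singularity.
#'
#' @param omega_body length-3 angular velocity in the body frame (rad/s).
#' @param angles length-3 numeric `c(psi, theta, phi)` (radians).
#' @return named numeric vector `c(psi_dot, theta_dot, phi_dot)` (rad/s).
#' @export
euler_rate <- function(omega_body, angles) {
  stopifnot(length(omega_body) == 3, length(angles) == 3)
  theta <- angles[2]; phi <- angles[3]
  cth <- cos(theta)
  if (abs(cth) <= 1e-6)
    stop("gimbal lock: |cos(theta)| <= 1e-6, Euler-angle rates are singular")
  p <- omega_body[1]; q <- omega_body[2]; r <- omega_body[3]
  sph <- sin(phi); cph <- cos(phi)
  c(psi_dot   = (q * sph + r * cph) / cth,
    theta_dot = q * cph - r * sph,
    phi_dot   = p + (q * sph + r * cph) * tan(theta))
}
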