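# Quasi-steady blade-element forces and torques.
#
# These are the reference (pure R) implementations of every force/torque in
# the rigid-body balance. The time integrator uses an equivalent compiled
# core for speed; tests assert that the two agree to near machine precision.

plate_direction_body <- function(placement) {
  cbind(cos(placement$lambda),
        sin(placement$lambda) * cos(placement$eps),
        sin(placement$lambda) * sin(placement$eps))
}

#' Per-ctene propulsive forces (global frame)
#'
#' Drag-based propulsion of each oscillating plate: the force on the body is
#' the negative of the quasi-steady drag on the plate,
#' `-(rho * w / 2) * y_A * C_A * |V_body + u|^2 * u / |u|`,
#' where `u` is the plate velocity in the global frame and `C_A` is evaluated
#' at the instantaneous plate Reynolds number. Plates with zero oscillatory
#' speed contribute nothing.
#'
#' @param placements a [place_ctenes()] table (or a subset of its rows).
#' @param states data.frame of tip states, one row per placement
#'   (see [tip_state()]).
#' @param body_vel length-3 body velocity in the global frame (m/s).
#' @param R global-to-body rotation matrix.
#' @param fluid a [fluid_properties()] object.
#' @param coeffs a [default_coefficients()] object.
#' @return n x 3 matrix of global-frame forces (N), one row per ctene.
#' @export
ctene_forces <- function(placements, states, body_vel, R, fluid, coeffs) {
  stopifnot(nrow(placements) == nrow(states))
  if (any(!is.finite(as.matrix(states[c("x_A_dot", "y_A")]))) ||
      any(!is.finite(body_vel)))
    stop("non-finite input to ctene_forces")
  d_body <- plate_direction_body(placements)      # n x 3 unit directions
  u <- (d_body * states$x_A_dot) %*% R            # = t(R^T %*% (xdot * d'))
  F <- matrix(0, nrow(placements), 3)
  active <- abs(states$x_A_dot) > 0
  if (!any(active)) return(F)
  u_a <- u[active, , drop = FALSE]
  speed <- abs(states$x_A_dot[active])
  Re_p <- speed * states$y_A[active] / fluid$nu
  C_A <- plate_drag_coefficient(Re_p, coeffs)
  rel <- sweep(u_a, 2, body_vel, "+")
  rel2 <- rowSums(rel^2)
  uhat <- u_a / speed
  F[active, ] <- -(fluid$rho * states$w[active] / 2) *
    states$y_A[active] * C_A * rel2 * uhat
  F
}

#' Propulsive force of one ctene row
#'
#' Sum of the per-ctene forces over the plates of a single row (the row's
#' placements and phase-lagged tip states are supplied by the caller).
#'
#' @inheritParams ctene_forces
#' @return length-3 global-frame force (N).
#' @export
row_force <- function(placements, states, body_vel, R, fluid, coeffs) {
  colSums(ctene_forces(placements, states, body_vel, R, fluid, coeffs))
}

#' Net propulsive force
#'
#' Vector sum of the row forces over all eight ctene rows.
#'
#' @param rows list (or matrix with one row per ctene row) of length-3 forces.
#' @return length-3 global-frame force (N).
#' @export
net_force <- function(rows) {
  if (is.list(rows)) rows <- do.call(rbind, rows)
  colSums(rows)
}

#' Net propulsive torque (body frame)
#'
#' Cross product of each ctene's body-frame position with its propulsive
#' force rotated into the body frame, summed over all ctenes.
#'
#' @param placements a [place_ctenes()] table.
#' @param forces_global n x 3 matrix of per-ctene global-frame forces (N).
#' @param R global-to-body rotation matrix.
#' @return length-3 body-frame torque (N m).
#' @export
propulsive_torque <- function(placements, forces_global, R) {
  stopifnot(nrow(placements) == nrow(forces_global))
  Fb <- forces_global %*% t(R)                    # rotate into body frame
  r <- as.matrix(placements[, c("x", "y", "z")])
  c(sum(r[, 2] * Fb[, 3] - r[, 3] * Fb[, 2]),
    sum(r[, 3] * Fb[, 1] - r[, 1] * Fb[, 3]),
    sum(r[, 1] * Fb[, 2] - r[, 2] * Fb[, 1]))
}

#' Body drag force
#'
#' Component-wise quadratic drag on the translating spheroid, evaluated in
#' the body frame with flow-normal areas `pi a^2` (axial) and `pi a b`
#' (lateral) and the speed-dependent coefficients of
#' [body_drag_coefficients()], then rotated back to the global frame.
#'
#' @param body_vel length-3 global-frame velocity (m/s).
#' @param R global-to-body rotation matrix.
#' @param body a [build_body()] object.
#' @param fluid a [fluid_properties()] object.
#' @param coeffs a [default_coefficients()] object.
#' @return length-3 global-frame force (N).
#' @export
body_drag <- function(body_vel, R, body, fluid, coeffs) {
  speed <- sqrt(sum(body_vel^2))
  if (speed == 0) return(c(0, 0, 0))
  vb <- as.numeric(R %*% body_vel)
  C <- body_drag_coefficients(speed * 2 * body$b / fluid$nu, coeffs)
  A <- pi * c(body$a^2, body$a * body$b, body$a * body$b)
  Cv <- c(C$par, C$perp, C$perp)
  Fb <- -(fluid$rho / 2) * A * Cv * speed * vb
  as.numeric(crossprod(R, Fb))
}

#' Acceleration-reaction (added-mass) force
#'
#' `-rho * V * diag(Cm_par, Cm_perp, Cm_perp)` applied to the body-frame
#' acceleration and rotated back to the global frame.
#'
#' @param body_acc length-3 global-frame acceleration (m/s^2).
#' @inheritParams body_drag
#' @return length-3 global-frame force (N).
#' @export
added_mass_force <- function(body_acc, R, body, fluid, coeffs) {
  Cm <- added_mass_coefficients(coeffs)
  ab <- as.numeric(R %*% body_acc)
  Fb <- -fluid$rho * body$V * c(Cm$par, Cm$perp, Cm$perp) * ab
  as.numeric(crossprod(R, Fb))
}

#' Opposing (resistive) torque
#'
#' Quadratic rotational resistance of the spheroid,
#' `-(rho/2) (d_e/2)^5 sgn(omega_i) C_R_i omega_i^2` per body-frame
#' component, with the roll coefficient on the symmetry axis and the
#' pitch/yaw coefficient on the transverse axes. Each component always
#' opposes its angular-velocity component.
#'
#' @param omega_body length-3 body-frame angular velocity (rad/s).
#' @inheritParams body_drag
#' @return length-3 body-frame torque (N m).
#' @export
opposing_torque <- function(omega_body, body, fluid, coeffs) {
  r_e <- body$d_e / 2
  out <- numeric(3)
  G <- c("par", "perp", "perp")
  for (i in 1:3) {
    w <- omega_body[i]
    if (w == 0) next
    C <- rotation_torque_coefficients(abs(w) * r_e^2 / fluid$nu, coeffs)[[G[i]]]
    out[i] <- -(fluid$rho / 2) * r_e^5 * sign(w) * C * w^2
  }
  out
}

#' Reynolds numbers of body and appendage
#'
#' Body Reynolds number `Re_b = U * L / nu` and the oscillatory appendage
#' Reynolds number `Re_omega = 2 * pi * f * l^2 / nu`.
#'
#' @param U swimming speed (m/s).
#' @param L body length (m).
#' @param f beat frequency (Hz).
#' @param l ctene length (m).
#' @param nu kinematic viscosity (m^2/s).
#' @return named numeric vector `c(Re_b, Re_omega)`.
#' @export
#' @examples
#' reynolds(U = 2.7 * 7.8e-3, L = 7.8e-3, f = 34, l = 0.5e-3, nu = 1.05e-6)
reynolds <- function(U, L, f, l, nu) {
  stopifnot(U >= 0, L > 0, f >= 0, l > 0, nu > 0)
  c(Re_b = U * L / nu, Re_omega = 2 * pi * f * l^2 / nu)
}
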