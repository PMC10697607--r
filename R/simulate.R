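# Time integration of the coupled translational/rotational dynamics.
#
# Translation: (m I + rho V R^T diag(Cm) R) Xdotdot = F_net + F_D
# (the acceleration-reaction force moved to the left-hand side as an
# effective mass matrix). Rotation: I omega_dot = T_net' + T_op' - omega x
# (I omega). Fixed-step classical RK4 keeps every run bit-reproducible;
# the step is 1/200 of the shortest active beat period.

build_core_params <- function(placements, program, beat, morph, body, fluid,
                              coeffs) {
  f_row <- program$freqs
  f <- f_row[placements$row_id]
  offset <- ifelse(f > 0, (placements$k - 1) * beat$P_L / f, 0)
  t_p <- ifelse(f > 0, (1 - beat$Ta) / (2 * f), Inf)
  t_r <- ifelse(f > 0, (1 + beat$Ta) / (2 * f), Inf)
  list(d_body = plate_direction_body(placements),
       r_body = as.matrix(placements[, c("x", "y", "z")]),
       f = f, offset = offset, t_p = t_p, t_r = t_r,
       direction = program$direction,
       a_x = morph$l * sin(beat$Phi * pi / 360),
       c_y = morph$l * (1 - beat$Sa / 2),
       a_y = morph$l * beat$Sa / 2,
       rho = fluid$rho, nu = fluid$nu, w_plate = 0.5 * morph$l,
       C_inf = coeffs$C_inf, alpha_A = coeffs$alpha_A,
       Re_lo = coeffs$Re_band[1], Re_hi = coeffs$Re_band[2],
       L_B = morph$L_B,
       area_par = pi * body$a^2, area_perp = pi * body$a * body$b,
       K_par = coeffs$K_par, K_perp = coeffs$K_perp,
       c1 = coeffs$c1, c2 = coeffs$c2,
       m = body$m, rhoV = fluid$rho * body$V,
       Cm_par = coeffs$Cm_par, Cm_perp = coeffs$Cm_perp,
       r_e = body$d_e / 2,
       G_par = coeffs$G_par, G_perp = coeffs$G_perp,
       c3 = coeffs$c3, c4 = coeffs$c4,
       I1 = body$I[1, 1], I2 = body$I[2, 2])
}

# flatten a 12- or 18-component state to the 12 output columns (Euler angles
# extracted from the rotation block for the DCM form)
state_to_sample_row <- function(state) {
  if (length(state) == 12) return(state)
  R <- matrix(state[7:15], 3, 3, byrow = TRUE)
  c(state[1:6],
    atan2(R[1, 2], R[1, 1]), asin(max(-1, min(1, -R[1, 3]))),
    atan2(R[2, 3], R[3, 3]), state[16:18])
}

samples_to_trajectory <- function(samples, morph, program, beat, dt_step,
                                  stride) {
  traj <- as.data.frame(samples)
  names(traj) <- c("t", "x", "y", "z", "vx", "vy", "vz",
                   "psi", "theta", "phi", "wx", "wy", "wz")
  structure(traj,
            class = c("cteno_trajectory", "data.frame"),
            L = morph$L_B,
            dt = dt_step * stride,
            dt_step = dt_step,
            f_max = max(program$freqs),
            mode_label = program$mode_label,
            direction = program$direction,
            beat = unclass(beat)[c("f", "Phi", "Ta", "Sa", "P_L")])
}

#' @export
print.cteno_trajectory <- function(x, ...) {
  cat(sprintf("Swimming trajectory [%s, direction %+d]: %d samples, t in [%.3g, %.3g] s\n",
              attr(x, "mode_label"), attr(x, "direction"), nrow(x),
              x$t[1], x$t[nrow(x)]))
  cat(sprintf("  displacement %.3g mm (%.3g body lengths)\n",
              1e3 * sqrt(sum((x[nrow(x), c("x", "y", "z")] -
                              x[1, c("x", "y", "z")])^2)),
              sqrt(sum((x[nrow(x), c("x", "y", "z")] -
                        x[1, c("x", "y", "z")])^2)) / attr(x, "L")))
  invisible(x)
}

#' Time derivative of the rigid-body state
#'
#' Reference (pure R) evaluation of the full force/torque balance at one
#' instant: propulsive forces of all plates, body drag, the effective-mass
#' solve for the translational acceleration, opposing and gyroscopic torques,
#' and the Euler-angle kinematics. Used for testing the compiled integrator
#' core against the exported force functions.
#'
#' @param t time (s).
#' @param state length-12 numeric: global position (3), global velocity (3),
#'   Euler angles `psi, theta, phi`, body-frame angular velocity (3).
#' @param placements a [place_ctenes()] table.
#' @param program a [row_frequency_program()].
#' @param beat a [beat_params()] object (its `f` is overridden per row by the
#'   program).
#' @param morph,body,fluid,coeffs model objects.
#' @return length-12 state derivative.
#' @export
state_derivative <- function(t, state, placements, program, beat, morph,
                             body, fluid, coeffs) {
  stopifnot(length(state) == 12)
  V <- state[4:6]; angles <- state[7:9]; omega <- state[10:12]
  R <- build_rotation_matrix(angles[1], angles[2], angles[3])
  f <- program$freqs[placements$row_id]
  st <- do.call(rbind, lapply(seq_len(nrow(placements)), function(i) {
    bp <- beat_params(f = f[i], Phi = beat$Phi, Ta = beat$Ta, Sa = beat$Sa,
                      P_L = beat$P_L, direction = program$direction)
    tip_state(t, bp, morph$l, phase_offset(placements$k[i], bp))
  }))
  Fc <- ctene_forces(placements, st, V, R, fluid, coeffs)
  F_net <- net_force(Fc)
  tau <- propulsive_torque(placements, Fc, R)
  F <- F_net + body_drag(V, R, body, fluid, coeffs)
  Cm <- c(coeffs$Cm_par, coeffs$Cm_perp, coeffs$Cm_perp)
  M <- body$m * diag(3) + fluid$rho * body$V * crossprod(R * sqrt(Cm))
  acc <- solve(M, F)
  Top <- opposing_torque(omega, body, fluid, coeffs)
  Iv <- diag(body$I)
  gyro <- c((Iv[3] - Iv[2]) * omega[2] * omega[3],
            (Iv[1] - Iv[3]) * omega[3] * omega[1],
            (Iv[2] - Iv[1]) * omega[1] * omega[2])
  er <- euler_rate(omega, angles)
  unname(c(V, acc, er, (tau + Top - gyro) / Iv))
}

#' Simulate a swimming maneuver
#'
#' Integrate the self-propelled rigid-body dynamics under a per-row frequency
#' program, starting from rest at the origin with the oral axis along +x.
#'
#' Halting policies:
#' \describe{
#'   \item{"none"}{run for exactly `duration` seconds.}
#'   \item{"rl_steady"}{run until the trailing 2-s mean normalized radius of
#'     curvature either exceeds the straight-swimming clamp (10) or changes
#'     by less than 1\% between consecutive beat cycles, up to
#'     `max_duration`.}
#'   \item{"speed_steady"}{run until the trailing 2-s mean speed changes by
#'     less than 0.1\% between consecutive beat cycles (terminal-speed
#'     plateau), up to `max_duration`.}
#' }
#'
#' @param program a [row_frequency_program()] or [assign_mode()] result.
#' @param morph a [morphometry()] object.
#' @param beat a [beat_params()] object; its `f` and `direction` fields are
#'   superseded by the program.
#' @param fluid a [fluid_properties()] object.
#' @param coeffs a [default_coefficients()] object, or `NULL` for defaults.
#' @param duration simulated time (s) for `halting = "none"`.
#' @param halting halting policy, see Details.
#' @param max_duration hard cap (s) for the steady-state policies.
#' @param stride output sampling stride in integrator steps.
#' @param steps_per_cycle integrator steps per beat cycle of the fastest
#'   active row (fixed-step RK4); the default resolves each power stroke
#'   with 70 steps.
#' @param state0 optional length-12 initial state (default: rest at origin).
#' @return a `cteno_trajectory` data.frame with columns `t, x, y, z, vx, vy,
#'   vz, psi, theta, phi, wx, wy, wz` and attributes `L` (body length),
#'   `dt` (sample interval), `halted` and `mode_label`.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_swim(assign_mode("mode1", 30, 0), duration = 0.25)
#' maneuver_metrics(tr)
#' }
simulate_swim <- function(program, morph = morphometry(),
                          beat = beat_params(), fluid = fluid_properties(),
                          coeffs = NULL, duration = 1,
                          halting = c("none", "rl_steady", "speed_steady"),
                          max_duration = 10, stride = 5L,
                          steps_per_cycle = 200L, state0 = NULL) {
  halting <- match.arg(halting)
  stopifnot(inherits(program, "cteno_program"), duration > 0)
  body <- build_body(morph, fluid)
  if (is.null(coeffs)) coeffs <- default_coefficients(body$a, body$b)
  placements <- place_ctenes(morph)
  if (is.null(state0)) state0 <- rep(0, 12)

  if (all(program$freqs == 0)) {
    samples <- cbind(c(0, duration),
                     matrix(rep(state0, each = 2), nrow = 2))
    tr <- samples_to_trajectory(samples, morph, program, beat, duration, 1L)
    attr(tr, "halted") <- "none"
    return(tr)
  }

  pars <- build_core_params(placements, program, beat, morph, body, fluid,
                            coeffs)
  f_max <- max(program$freqs)
  steps_per_cycle <- as.integer(steps_per_cycle)
  dt <- 1 / (steps_per_cycle * f_max)
  stride <- as.integer(stride)

  if (halting == "none") {
    nsteps <- max(1L, as.integer(round(duration / dt)))
    res <- .cteno_rk4_cpp(state0, 0L, nsteps, dt, stride, pars)
    tr <- samples_to_trajectory(res$samples, morph, program, beat, dt, stride)
    attr(tr, "halted") <- "none"
    return(tr)
  }

  # steady-state policies: advance one beat cycle at a time and test the
  # trailing-window statistic
  cycle_steps <- steps_per_cycle
  window <- 2                       # trailing window (s)
  tol <- if (halting == "rl_steady") 0.01 else 0.001
  chunks <- list()
  state <- state0
  steps_done <- 0L
  t_now <- 0
  prev_stat <- NA_real_
  halted <- "cap"
  n_cycles <- ceiling(max_duration * f_max)
  for (cyc in seq_len(n_cycles)) {
    res <- .cteno_rk4_cpp(state, steps_done, cycle_steps, dt, stride, pars)
    samples <- res$samples
    state <- res$state
    steps_done <- steps_done + cycle_steps
    t_now <- samples[nrow(samples), 1]
    chunks[[cyc]] <- if (cyc == 1) samples else samples[-1, , drop = FALSE]
    if (t_now + 1e-9 >= window) {
      all_s <- do.call(rbind, chunks)
      tail_tr <- samples_to_trajectory(
        all_s[all_s[, 1] >= t_now - window, , drop = FALSE],
        morph, program, beat, dt, stride)
      stat <- if (halting == "rl_steady") {
        turning_radius_state(tail_tr, L = morph$L_B, startup_cycles = 0)$RL_bar
      } else {
        mean_speed(tail_tr, L = morph$L_B, startup_cycles = 0)
      }
      if (halting == "rl_steady" && stat >= 10) { halted <- "straight"; break }
      if (!is.na(prev_stat) && prev_stat > 0 &&
          abs(stat - prev_stat) / prev_stat < tol) { halted <- "steady"; break }
      prev_stat <- stat
    }
    if (t_now + dt * cycle_steps > max_duration + 1e-9) { halted <- "cap"; break }
  }
  tr <- samples_to_trajectory(do.call(rbind, chunks), morph, program, beat,
                              dt, stride)
  attr(tr, "halted") <- halted
  tr
}

#' Replay a per-row frequency schedule
#'
#' Integrate the dynamics under time-varying per-row beat frequencies, held
#' stepwise-constant per beat cycle (the schedule is sampled with constant
#' interpolation at the start of each cycle of the currently fastest active
#' row). A constant schedule reproduces [simulate_swim()] exactly.
#'
#' @param schedule data.frame with a time column `t` (s) and eight frequency
#'   columns `f1` ... `f8` (Hz), rows in increasing time.
#' @param direction +1 forward, -1 backward power stroke.
#' @param duration simulated time (s); defaults to the schedule's last time.
#' @inheritParams simulate_swim
#' @return a `cteno_trajectory`.
#' @export
replay <- function(schedule, direction = 1, morph = morphometry(),
                   beat = beat_params(), fluid = fluid_properties(),
                   coeffs = NULL, duration = NULL, stride = 5L) {
  fcols <- paste0("f", 1:8)
  stopifnot(is.data.frame(schedule), "t" %in% names(schedule),
            all(fcols %in% names(schedule)))
  if (any(as.matrix(schedule[fcols]) < 0))
    stop("schedule frequencies must be >= 0")
  if (is.unsorted(schedule$t, strictly = TRUE))
    stop("schedule times must be strictly increasing")
  if (is.null(duration)) duration <- max(schedule$t)
  stopifnot(duration > 0)
  body <- build_body(morph, fluid)
  if (is.null(coeffs)) coeffs <- default_coefficients(body$a, body$b)
  placements <- place_ctenes(morph)
  f_overall <- max(as.matrix(schedule[fcols]))
  if (f_overall == 0)
    return(simulate_swim(row_frequency_program(rep(0, 8), direction, "replay"),
                         morph, beat, fluid, coeffs, duration))
  dt <- 1 / (200 * f_overall)
  lookup <- function(tq) {
    vapply(fcols, function(cn)
      stats::approx(schedule$t, schedule[[cn]], xout = tq,
                    method = "constant", rule = 2)$y,
      numeric(1))
  }
  state <- rep(0, 12)
  steps_done <- 0L
  t_now <- 0
  chunks <- list()
  i <- 0L
  last_prog <- NULL
  while (t_now < duration - 1e-12) {
    i <- i + 1L
    freqs <- lookup(t_now)
    prog <- row_frequency_program(freqs, direction, "replay")
    last_prog <- prog
    f_act <- max(freqs)
    chunk_t <- if (f_act > 0) 1 / f_act else duration - t_now
    nsteps <- max(1L, as.integer(round(min(chunk_t, duration - t_now) / dt)))
    if (f_act == 0) {
      row <- state_to_sample_row(state)
      samples <- cbind(c(steps_done, steps_done + nsteps) * dt,
                       rbind(row, row))
    } else {
      pars <- build_core_params(placements, prog, beat, morph, body, fluid,
                                coeffs)
      res <- .cteno_rk4_cpp(state, steps_done, nsteps, dt, stride, pars)
      samples <- res$samples
      state <- res$state
    }
    steps_done <- steps_done + nsteps
    t_now <- steps_done * dt
    chunks[[i]] <- if (i == 1L) samples else samples[-1, , drop = FALSE]
  }
  tr <- samples_to_trajectory(do.call(rbind, chunks), morph, last_prog, beat,
                              dt, stride)
  attr(tr, "mode_label") <- "replay"
  attr(tr, "halted") <- "none"
  tr
}
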