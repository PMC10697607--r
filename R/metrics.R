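# Maneuverability and agility metrics.
#
# Maneuverability is the mean normalized radius of curvature R/L (smaller =
# tighter turns), clamped at 10, which is treated as straight swimming.
# Agility is the mean translational speed in body lengths per second.
# Positions are smoothed with a centered moving average spanning one beat
# period before differentiation, removing the intra-beat wobble that would
# otherwise bias the radius of curvature low; the first two beat cycles
# (startup transient) are excluded from the analysis window.

metric_window <- function(traj, startup_cycles) {
  f_max <- attr(traj, "f_max")
  t0 <- traj$t[1]
  if (!is.null(f_max) && is.finite(f_max) && f_max > 0 && startup_cycles > 0)
    t0 <- traj$t[1] + startup_cycles / f_max
  traj[traj$t >= t0 - 1e-12, , drop = FALSE]
}

smooth_positions <- function(traj) {
  P <- as.matrix(traj[, c("x", "y", "z")])
  f_max <- attr(traj, "f_max")
  dt <- attr(traj, "dt")
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    dt <- stats::median(diff(traj$t))
  if (is.null(f_max) || !is.finite(f_max) || f_max <= 0) return(list(P = P, dt = dt))
  n_w <- round(1 / (f_max * dt))
  if (n_w %% 2 == 0) n_w <- n_w + 1
  if (n_w < 3 || n_w >= nrow(P)) return(list(P = P, dt = dt))
  Ps <- apply(P, 2, function(col)
    as.numeric(stats::filter(col, rep(1 / n_w, n_w), sides = 2)))
  keep <- !is.na(Ps[, 1])
  list(P = Ps[keep, , drop = FALSE], dt = dt)
}

#' Mean swimming speed
#'
#' Path length divided by elapsed time, normalized by body length: the
#' agility metric, in body lengths per second. The path length is the sum of
#' chord lengths between consecutive samples.
#'
#' @param traj a `cteno_trajectory` (or any data.frame with columns
#'   `t, x, y, z`).
#' @param L body length (m); defaults to the trajectory's `L` attribute.
#' @param startup_cycles beat cycles excluded from the start of the analysis
#'   window (transient from rest).
#' @return mean speed (body lengths per second).
#' @export
#' @examples
#' tr <- make_fixture("line", list(speed = 10e-3, L = 7.8e-3), n = 50)
#' mean_speed(tr)   # 10 / 7.8 BL/s
mean_speed <- function(traj, L = attr(traj, "L"), startup_cycles = 2) {
  stopifnot(!is.null(L), L > 0)
  traj <- metric_window(traj, startup_cycles)
  if (nrow(traj) < 2) stop("mean_speed needs at least 2 samples")
  P <- as.matrix(traj[, c("x", "y", "z")])
  path <- sum(sqrt(rowSums(diff(P)^2)))
  elapsed <- traj$t[nrow(traj)] - traj$t[1]
  if (elapsed <= 0) stop("degenerate trajectory: no elapsed time")
  path / elapsed / L
}

#' Mean normalized radius of curvature
#'
#' The maneuverability metric: the per-sample radius of curvature
#' `R = |v|^3 / |v x a|` from central differences of the (beat-period
#' smoothed) positions, normalized by body length, clamped at `clamp`, and
#' averaged over the analysis window. A trajectory whose curvature is below
#' machine tolerance everywhere (a straight line) returns the clamp value
#' with `straight_flag = TRUE`.
#'
#' @inheritParams mean_speed
#' @param clamp upper clamp on R/L; values at or above it count as straight
#'   swimming.
#' @return list with `RL_bar`, `straight_flag` and the analysis `window`
#'   (start/end times, s).
#' @export
#' @examples
#' circ <- make_fixture("circle", list(radius = 5e-3, omega = 2, L = 7.8e-3),
#'                      n = 200)
#' curvature_radius(circ)$RL_bar * 7.8e-3   # ~ 5e-3 m
curvature_radius <- function(traj, L = attr(traj, "L"), clamp = 10,
                             startup_cycles = 2) {
  stopifnot(!is.null(L), L > 0)
  traj <- metric_window(traj, startup_cycles)
  if (nrow(traj) < 3) stop("curvature_radius needs at least 3 samples")
  sm <- smooth_positions(traj)
  P <- sm$P; h <- sm$dt
  n <- nrow(P)
  if (n < 3) stop("too few samples after smoothing")
  i <- 2:(n - 1)
  v <- (P[i + 1, , drop = FALSE] - P[i - 1, , drop = FALSE]) / (2 * h)
  a <- (P[i + 1, , drop = FALSE] - 2 * P[i, , drop = FALSE] +
          P[i - 1, , drop = FALSE]) / h^2
  cr <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
              v[, 3] * a[, 1] - v[, 1] * a[, 3],
              v[, 1] * a[, 2] - v[, 2] * a[, 1])
  vmag <- sqrt(rowSums(v^2))
  cmag <- sqrt(rowSums(cr^2))
  ok <- vmag > 0
  if (!any(ok))
    return(list(RL_bar = clamp, straight_flag = TRUE,
                window = range(traj$t)))
  R <- ifelse(cmag[ok] > vmag[ok]^3 * 1e-12, vmag[ok]^3 / cmag[ok], Inf)
  RL <- pmin(R / L, clamp)
  out <- mean(RL)
  list(RL_bar = out, straight_flag = out >= clamp - 1e-12,
       window = range(traj$t))
}

#' Turning radius from the rigid-body state
#'
#' Per-sample instantaneous turning radius `R = |v| / |omega|` (translational
#' speed over angular speed), normalized by body length, clamped and
#' averaged. For a rigid body in a steady turn this equals the path radius of
#' curvature, but unlike the path-geometry estimator it is unbiased by the
#' spin-up transient of a from-rest maneuver (speed and turning rate grow
#' together, so their ratio is meaningful from the first beat) and by
#' intra-beat wobble. It is the metric used for simulated maneuvers, where
#' the angular velocity is part of the state; path-only inputs (landmark
#' tracks, fixtures) fall back to [curvature_radius()].
#'
#' @inheritParams mean_speed
#' @param clamp upper clamp on R/L (straight swimming).
#' @return list with `RL_bar`, `straight_flag` and `window`.
#' @export
turning_radius_state <- function(traj, L = attr(traj, "L"), clamp = 10,
                                 startup_cycles = 2) {
  stopifnot(!is.null(L), L > 0)
  if (!all(c("vx", "vy", "vz", "wx", "wy", "wz") %in% names(traj)))
    stop("state-based turning radius needs velocity and angular-velocity columns")
  traj <- metric_window(traj, startup_cycles)
  if (nrow(traj) < 1) stop("empty analysis window")
  vmag <- sqrt(traj$vx^2 + traj$vy^2 + traj$vz^2)
  wmag <- sqrt(traj$wx^2 + traj$wy^2 + traj$wz^2)
  RL <- ifelse(wmag > vmag / (clamp * L), vmag / wmag / L, clamp)
  out <- mean(pmin(RL, clamp))
  list(RL_bar = out, straight_flag = out >= clamp - 1e-12,
       window = range(traj$t))
}

#' Maneuverability and agility of a trajectory
#'
#' Convenience wrapper computing both metrics over the same analysis window.
#' With `method = "auto"` (default) the maneuverability metric is the
#' state-based turning radius ([turning_radius_state()]) when the trajectory
#' carries velocity and angular-velocity columns (simulated maneuvers), and
#' the path-geometry estimator ([curvature_radius()]) otherwise.
#'
#' @inheritParams curvature_radius
#' @param method `"auto"`, `"state"` or `"path"`.
#' @return object of class `cteno_metrics`: list with `V_bar` (BL/s),
#'   `RL_bar`, `straight_flag` and `window`.
#' @export
maneuver_metrics <- function(traj, L = attr(traj, "L"), clamp = 10,
                             startup_cycles = 2,
                             method = c("auto", "state", "path")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (all(c("wx", "wy", "wz") %in% names(traj))) "state" else "path"
  cr <- if (method == "state") {
    turning_radius_state(traj, L = L, clamp = clamp,
                         startup_cycles = startup_cycles)
  } else {
    curvature_radius(traj, L = L, clamp = clamp,
                     startup_cycles = startup_cycles)
  }
  structure(list(V_bar = mean_speed(traj, L = L,
                                    startup_cycles = startup_cycles),
                 RL_bar = cr$RL_bar, straight_flag = cr$straight_flag,
                 window = cr$window),
            class = "cteno_metrics")
}

#' @export
print.cteno_metrics <- function(x, ...) {
  cat(sprintf("Maneuver metrics over t in [%.3g, %.3g] s\n",
              x$window[1], x$window[2]))
  cat(sprintf("  V_bar  = %.4g BL/s (agility)\n", x$V_bar))
  cat(sprintf("  RL_bar = %.4g%s (maneuverability)\n", x$RL_bar,
              if (x$straight_flag) " [straight]" else ""))
  invisible(x)
}

#' Assemble a Maneuverability-Agility Plot table
#'
#' Collect per-run metrics into the MAP table: one row per run with the mode
#' label, frequencies and the two metrics. Attributes `best_turn` and
#' `fastest` give the minimum-RL_bar and maximum-V_bar rows.
#'
#' @param results data.frame with columns `mode`, `f_out`, `f_in`,
#'   `direction`, `V_bar`, `RL_bar` (as produced by [run_sweep()]), or a list
#'   of such rows.
#' @return data.frame of class `cteno_map`.
#' @export
build_map <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  stopifnot(nrow(results) >= 1,
            all(c("V_bar", "RL_bar") %in% names(results)))
  structure(results,
            class = c("cteno_map", "data.frame"),
            best_turn = results[which.min(results$RL_bar), , drop = FALSE],
            fastest = results[which.max(results$V_bar), , drop = FALSE])
}

#' @export
print.cteno_map <- function(x, ...) {
  cat(sprintf("Maneuverability-Agility table: %d runs\n", nrow(x)))
  bt <- attr(x, "best_turn"); ft <- attr(x, "fastest")
  cat(sprintf("  sharpest turn: RL_bar = %.3g at V_bar = %.3g BL/s\n",
              bt$RL_bar, bt$V_bar))
  cat(sprintf("  fastest:       V_bar = %.3g BL/s at RL_bar = %.3g\n",
              ft$V_bar, ft$RL_bar))
  invisible(x)
}
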