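#' Analytic trajectory and landmark fixtures
#'
#' Generate trajectories with exactly known speed and radius of curvature,
#' used as oracles for the metric estimators, plus a rigidly moving landmark
#' triangle with a prescribed pose for testing canonicalization.
#'
#' Kinds and their parameters (all lengths m, times s):
#' \describe{
#'   \item{line}{`speed`, optional unit `dir` (default +x), `L`,
#'     `duration`; `R = Inf`.}
#'   \item{circle}{`radius` (default 5 mm), angular rate `omega` (default
#'     2 rad/s), `L`, optional `turns`; `R = radius`.}
#'   \item{helix}{`radius` (default 4 mm), `omega` (default 2 rad/s),
#'     `pitch` (rise per turn, default 2 mm), `L`;
#'     `R = radius * (1 + (pitch / (2 pi radius))^2)`.}
#'   \item{landmark_pose}{`yaw`, `pitch`, `roll` (rad), `speed`, `L`,
#'     `offset` (initial position): a landmark triangle (apical organ and two
#'     tentacular bulbs) rigidly translated with the prescribed constant
#'     pose.}
#' }
#'
#' @param kind one of `"line"`, `"circle"`, `"helix"`, `"landmark_pose"`.
#' @param params named list of parameters, see Details.
#' @param n number of samples (>= 3).
#' @return a `cteno_trajectory`, or a `cteno_landmarks` table for
#'   `"landmark_pose"`.
#' @export
#' @examples
#' helix <- make_fixture("helix",
#'   list(radius = 4e-3, omega = 3, pitch = 2e-3, L = 7.8e-3), n = 400)
#' curvature_radius(helix)$RL_bar
make_fixture <- function(kind = c("line", "circle", "helix", "landmark_pose"),
                         params = list(), n = 200) {
  kind <- match.arg(kind)
  if (n < 3) stop("fixtures need n >= 3 samples")
  p <- params
  L <- if (!is.null(p$L)) p$L else 7.8e-3
  mk <- function(t, xyz) {
    traj <- data.frame(t = t, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    structure(traj, class = c("cteno_trajectory", "data.frame"),
              L = L, dt = t[2] - t[1], f_max = NA_real_,
              mode_label = paste0("fixture_", kind), direction = 1L)
  }
  if (kind == "line") {
    speed <- if (!is.null(p$speed)) p$speed else 1e-2
    dir <- if (!is.null(p$dir)) p$dir / sqrt(sum(p$dir^2)) else c(1, 0, 0)
    duration <- if (!is.null(p$duration)) p$duration else 1
    t <- seq(0, duration, length.out = n)
    return(mk(t, outer(t * speed, dir)))
  }
  if (kind == "circle") {
    radius <- if (!is.null(p$radius)) p$radius else 5e-3
    omega <- if (!is.null(p$omega)) p$omega else 2
    turns <- if (!is.null(p$turns)) p$turns else 1
    t <- seq(0, 2 * pi * turns / omega, length.out = n)
    return(mk(t, cbind(radius * cos(omega * t), radius * sin(omega * t), 0)))
  }
  if (kind == "helix") {
    radius <- if (!is.null(p$radius)) p$radius else 4e-3
    omega <- if (!is.null(p$omega)) p$omega else 2
    pitch <- if (!is.null(p$pitch)) p$pitch else 2e-3
    turns <- if (!is.null(p$turns)) p$turns else 1
    t <- seq(0, 2 * pi * turns / omega, length.out = n)
    return(mk(t, cbind(radius * cos(omega * t), radius * sin(omega * t),
                       pitch * omega * t / (2 * pi))))
  }
  # landmark_pose: rigid triangle moving at constant velocity, fixed pose
  yaw <- if (!is.null(p$yaw)) p$yaw else 0
  pitch <- if (!is.null(p$pitch)) p$pitch else 0
  roll <- if (!is.null(p$roll)) p$roll else 0
  speed <- if (!is.null(p$speed)) p$speed else 5e-3
  offset <- if (!is.null(p$offset)) p$offset else c(0, 0, 0)
  R <- build_rotation_matrix(yaw, pitch, roll)
  # body-frame landmark geometry: apical organ on the aboral pole, bulbs
  # symmetric about the sagittal plane in the tentacular plane
  ao_b <- c(-L / 2, 0, 0)
  b1_b <- c(L / 8, L / 4, 0)
  b2_b <- c(L / 8, -L / 4, 0)
  to_g <- function(v) as.numeric(crossprod(R, v))
  ao <- to_g(ao_b); b1 <- to_g(b1_b); b2 <- to_g(b2_b)
  vel <- to_g(c(speed, 0, 0))
  t <- seq(0, 1, length.out = n)
  shift <- outer(t, vel) + matrix(offset, n, 3, byrow = TRUE)
  lm <- data.frame(t = t,
                   apical_x = ao[1] + shift[, 1], apical_y = ao[2] + shift[, 2],
                   apical_z = ao[3] + shift[, 3],
                   bulb1_x = b1[1] + shift[, 1], bulb1_y = b1[2] + shift[, 2],
                   bulb1_z = b1[3] + shift[, 3],
                   bulb2_x = b2[1] + shift[, 1], bulb2_y = b2[2] + shift[, 2],
                   bulb2_z = b2[3] + shift[, 3])
  structure(lm, class = c("cteno_landmarks", "data.frame"),
            L = L, frame_rate = (n - 1) / (t[n] - t[1]))
}
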