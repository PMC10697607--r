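#' Beat-cycle parameters
#'
#' The five paddle control parameters of the oscillating-plate model plus the
#' metachronal phase lag and global power-stroke direction.
#'
#' Temporal asymmetry `Ta = (t_r - t_p) / (t_r + t_p)` sets the split of the
#' period `T = 1/f` into a fast power stroke of duration
#' `t_p = (1 - Ta) / (2 f)` and a slow recovery of duration
#' `t_r = (1 + Ta) / (2 f)`. Spatial asymmetry `Sa = A_e / A_o` is the area
#' enclosed by the tip path relative to its practical maximum (the largest
#' ellipse with the same stroke amplitude inscribed in the half-circle of
#' radius `l` swept by a rigid plate).
#'
#' Defaults are representative values for *Bolinopsis vitrea*:
#' amplitude 112 degrees, phase lag 13.2% of the period, Ta = Sa = 0.3.
#'
#' @param f beat frequency (Hz); 0 marks an inactive row.
#' @param Phi stroke amplitude (degrees), in (0, 180).
#' @param Ta temporal asymmetry, in (-1, 1).
#' @param Sa spatial asymmetry, in (0, 1].
#' @param P_L phase lag between adjacent ctenes as a fraction of the period.
#' @param direction +1 for forward swimming (power stroke sweeps the tip
#'   aborally, thrust oral-ward), -1 for reversed power stroke (backward
#'   swimming).
#' @return object of class `cteno_beat`, with derived `t_p`, `t_r`, `tau`.
#' @export
#' @examples
#' bp <- beat_params(f = 30)
#' bp$t_p * bp$f          # power-stroke fraction of the cycle
beat_params <- function(f = 20, Phi = 112, Ta = 0.3, Sa = 0.3,
                        P_L = 0.132, direction = 1) {
  if (!is.finite(f) || f < 0) stop("beat frequency must be >= 0")
  if (!(Phi > 0 && Phi < 180)) stop("stroke amplitude must lie in (0, 180) degrees")
  if (!(Ta > -1 && Ta < 1)) stop("temporal asymmetry must lie in (-1, 1)")
  if (!(Sa > 0 && Sa <= 1)) stop("spatial asymmetry must lie in (0, 1]")
  if (!(P_L >= 0 && P_L < 1)) stop("phase lag must lie in [0, 1) of the period")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  t_p <- if (f > 0) (1 - Ta) / (2 * f) else Inf
  t_r <- if (f > 0) (1 + Ta) / (2 * f) else Inf
  structure(list(f = f, Phi = Phi, Ta = Ta, Sa = Sa, P_L = P_L,
                 direction = direction, t_p = t_p, t_r = t_r,
                 tau = if (f > 0) P_L / f else 0),
            class = "cteno_beat")
}

#' @export
print.cteno_beat <- function(x, ...) {
  cat(sprintf(paste0("Beat parameters: f = %.3g Hz, Phi = %.4g deg, ",
                     "Ta = %.3g, Sa = %.3g, P_L = %.3g, direction = %+d\n"),
              x$f, x$Phi, x$Ta, x$Sa, x$P_L, x$direction))
  invisible(x)
}

#' Metachronal phase offset of the k-th ctene
#'
#' Ctene `k` (1 = most aboral) beats with a time delay `(k - 1) * tau`,
#' `tau = P_L / f`, producing an antiplectic metachronal wave: the wave of
#' beating travels from the aboral toward the oral end of the row, opposite
#' to the (aborally directed) power stroke.
#'
#' @param k 1-based ctene index within the row.
#' @param params a [beat_params()] object.
#' @return phase offset (s); 0 for an inactive row (`f = 0`).
#' @export
phase_offset <- function(k, params) {
  stopifnot(all(k >= 1))
  if (params$f == 0) return(rep(0, length(k)))
  (k - 1) * params$P_L / params$f
}

#' Instantaneous plate tip state
#'
#' Prescribed kinematics of a single ctene modelled as an oscillating flat
#' plate of time-varying length. The distal tip traces a closed ellipse once
#' per period: centered at `(0, l * (1 - Sa/2))` with horizontal semi-axis
#' `l * sin(Phi/2)` and vertical semi-axis `l * Sa / 2`, so the plate reaches
#' full extension `y_A = l` at mid power stroke and the enclosed tip-path
#' area equals `Sa` times its practical maximum. The upper arc (power stroke)
#' is traversed at constant parameter rate in time `t_p`, the lower arc
#' (recovery) in `t_r`. For `direction = +1` the power stroke sweeps the tip
#' aborally (`x_A` decreasing); `direction = -1` time-mirrors the traversal.
#'
#' @param t time (s); vectorized.
#' @param params a [beat_params()] object.
#' @param l ctene length (m).
#' @param phase_offset metachronal delay (s), see [phase_offset()].
#' @return data.frame with columns `x_A`, `y_A` (m), `x_A_dot`, `y_A_dot`
#'   (m/s) and `w` (plate width, `0.5 * l`).
#' @export
#' @examples
#' ts <- tip_state(seq(0, 1 / 30, length.out = 201), beat_params(f = 30), 5e-4)
#' max(abs(ts$x_A)) / 5e-4      # ~ sin(Phi / 2)
tip_state <- function(t, params, l, phase_offset = 0) {
  stopifnot(inherits(params, "cteno_beat"), l > 0)
  w <- 0.5 * l
  a_x <- l * sin(params$Phi * pi / 360)
  a_y <- l * params$Sa / 2
  c_y <- l * (1 - params$Sa / 2)
  if (params$f == 0) {
    z <- rep(0, length(t))
    return(data.frame(x_A = z, y_A = rep(c_y, length(t)),
                      x_A_dot = z, y_A_dot = z, w = rep(w, length(t))))
  }
  T <- 1 / params$f
  s <- (t - phase_offset) %% T
  if (params$direction < 0) s <- (T - s) %% T
  power <- s < params$t_p
  eta <- ifelse(power, pi * s / params$t_p,
                pi + pi * (s - params$t_p) / params$t_r)
  rate <- ifelse(power, pi / params$t_p, pi / params$t_r)
  if (params$direction < 0) rate <- -rate
  data.frame(x_A = a_x * cos(eta),
             y_A = c_y + a_y * sin(eta),
             x_A_dot = -a_x * sin(eta) * rate,
             y_A_dot = a_y * cos(eta) * rate,
             w = rep(w, length(t)))
}

#' Plate velocity in the global frame
#'
#' The plate slides along the meridian tangent at its station; in the body
#' frame the unit direction of increasing `x_A` is
#' `(cos(lambda), sin(lambda) cos(eps), sin(lambda) sin(eps))`, which is
#' rotated to the global frame with the transpose of the rotation matrix.
#'
#' @param state one-row tip state (see [tip_state()]).
#' @param R global-to-body rotation matrix.
#' @param placement one row of a [place_ctenes()] table (fields `lambda`,
#'   `eps`).
#' @return length-3 global-frame velocity (m/s) with norm `|x_A_dot|`.
#' @export
plate_velocity_global <- function(state, R, placement) {
  d_body <- c(cos(placement$lambda),
              sin(placement$lambda) * cos(placement$eps),
              sin(placement$lambda) * sin(placement$eps))
  as.numeric(crossprod(R, state$x_A_dot * d_body))
}
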