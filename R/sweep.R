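# Parameter-sweep experiments over the control strategies.

#' Run the turning-mode frequency sweep
#'
#' Simulate every (configuration, f_out, f_in) combination of
#' [enumerate_sweep()] -- 612 runs -- each from rest with the steady-state
#' halting rule (halt when the trailing 2-s mean R/L is steady or exceeds
#' 10), and collect the maneuverability/agility metrics into a MAP table.
#'
#' @param direction +1 forward, -1 backward power stroke.
#' @param morph,beat,fluid,coeffs model objects (defaults: population means
#'   and representative kinematics).
#' @param max_duration per-run hard cap (s).
#' @param progress print one line per run to standard error.
#' @return a [build_map()] table with one row per run: `mode`, `f_out`,
#'   `f_in`, `direction`, `V_bar`, `RL_bar`, `straight`, `halted`, `t_end`.
#' @export
run_sweep <- function(direction = 1, morph = morphometry(),
                      beat = beat_params(), fluid = fluid_properties(),
                      coeffs = NULL, max_duration = 10, progress = FALSE) {
  runs <- enumerate_sweep(direction)
  if (is.null(coeffs)) {
    body <- build_body(morph, fluid)
    coeffs <- default_coefficients(body$a, body$b)
  }
  res <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    prog <- assign_mode(r$mode, f_out = r$f_out, f_in = r$f_in,
                        direction = direction)
    tr <- simulate_swim(prog, morph, beat, fluid, coeffs,
                        halting = "rl_steady", max_duration = max_duration)
    mm <- maneuver_metrics(tr, L = morph$L_B)
    if (progress)
      message(sprintf("[%3d/%d] %s f_out=%g f_in=%g -> RL=%.3g V=%.3g (%s)",
                      i, nrow(runs), r$mode, r$f_out, r$f_in,
                      mm$RL_bar, mm$V_bar, attr(tr, "halted")))
    res[[i]] <- data.frame(mode = r$mode, f_out = r$f_out, f_in = r$f_in,
                           direction = direction, V_bar = mm$V_bar,
                           RL_bar = mm$RL_bar, straight = mm$straight_flag,
                           halted = attr(tr, "halted"),
                           t_end = tr$t[nrow(tr)])
  }
  build_map(do.call(rbind, res))
}

#' Run the independent row-subset experiment
#'
#' Simulate all 255 non-empty subsets of the eight rows beating at `f` for
#' `duration` seconds from rest (the hypothetical fully independent row
#' control), for each requested power-stroke direction, and collect metrics.
#'
#' @param f beat frequency of the active rows (Hz).
#' @param directions power-stroke directions to simulate (subset of
#'   `c(1, -1)`).
#' @param duration simulated time per run (s).
#' @inheritParams run_sweep
#' @param keep_trajectories return the canonicalized trajectories (for motor
#'   volumes) alongside the metrics.
#' @return data.frame with `subset` (bit mask), `n_rows`, `direction`,
#'   `V_bar`, `RL_bar`, `straight`; when `keep_trajectories = TRUE`, a list
#'   with elements `metrics` and `trajectories`.
#' @export
run_subsets <- function(f = 30, directions = c(1, -1), duration = 1,
                        morph = morphometry(), beat = beat_params(),
                        fluid = fluid_properties(), coeffs = NULL,
                        keep_trajectories = FALSE, progress = FALSE) {
  if (is.null(coeffs)) {
    body <- build_body(morph, fluid)
    coeffs <- default_coefficients(body$a, body$b)
  }
  res <- list(); trajs <- list(); n <- 0L
  for (dir in directions) {
    progs <- enumerate_subsets(f, direction = dir)
    for (j in seq_along(progs)) {
      n <- n + 1L
      tr <- simulate_swim(progs[[j]], morph, beat, fluid, coeffs,
                          duration = duration, halting = "none")
      mm <- maneuver_metrics(tr, L = morph$L_B)
      res[[n]] <- data.frame(subset = j, n_rows = length(attr(progs[[j]], "rows")),
                             direction = dir, V_bar = mm$V_bar,
                             RL_bar = mm$RL_bar, straight = mm$straight_flag)
      if (keep_trajectories) trajs[[n]] <- canonicalize(tr)
      if (progress && n %% 50 == 0)
        message(sprintf("[%d] subsets simulated", n))
    }
  }
  metrics <- do.call(rbind, res)
  if (keep_trajectories) list(metrics = metrics, trajectories = trajs)
  else metrics
}
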