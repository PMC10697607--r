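# Configuration, trajectory and landmark I/O.
#
# Configurations are YAML with nested blocks (morphometry, beat, fluid,
# control, simulation, output). Lengths are given in mm and angles in degrees
# at the configuration boundary and converted to SI internally. Every output
# file carries the configuration fingerprint (a 64-bit FNV-1a hash of the
# normalized configuration) so runs can be traced to their inputs.

config_fingerprint <- function(x) {
  bytes <- utf8ToInt(yaml::as.yaml(x))
  h <- 2166136261                       # 32-bit FNV-1a in double arithmetic
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (((h %/% 65536) * m) %% 65536) * 65536 + (h %% 65536) * m
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

known_keys <- list(
  top = c("morphometry", "beat", "fluid", "control", "simulation", "output"),
  morphometry = c("L_B_mm", "d_B_mm", "l_mm", "s", "n_S", "n_T",
                  "eps_S_deg", "eps_T_deg", "kappa_deg"),
  beat = c("Phi_deg", "Ta", "Sa", "P_L"),
  fluid = c("rho", "nu"),
  control = c("mode", "f_out", "f_in", "direction", "freqs", "rows", "f",
              "replay"),
  simulation = c("duration", "halting", "max_duration", "stride"),
  output = c("trajectory", "metrics", "stride")
)

check_keys <- function(block, name) {
  if (is.null(block)) return(invisible())
  bad <- setdiff(names(block), known_keys[[name]])
  if (length(bad))
    stop(sprintf("unknown key(s) in '%s' block: %s", name,
                 paste(bad, collapse = ", ")))
  invisible()
}

#' Read a run configuration
#'
#' Parse and validate a YAML run configuration. Omitted morphometry fields
#' default to the population means and omitted kinematic fields to the
#' representative beat parameters; an empty or missing control block defaults
#' to straight swimming (mode 4 at 20 Hz) with a notice. Unknown keys are
#' rejected with the offending key path.
#'
#' @param path path to a YAML configuration file.
#' @return object of class `cteno_config`: list with validated `morph`,
#'   `beat`, `fluid`, `program` (or `replay` schedule path), `simulation` and
#'   `output` blocks plus the configuration `fingerprint`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, "top")
  for (blk in names(raw)) check_keys(raw[[blk]], blk)

  g <- function(block, key, default) {
    v <- raw[[block]][[key]]
    if (is.null(v)) default else v
  }
  morph <- morphometry(
    L_B = g("morphometry", "L_B_mm", 7.8) * 1e-3,
    d_B = g("morphometry", "d_B_mm", 6.1) * 1e-3,
    l = g("morphometry", "l_mm", 0.5) * 1e-3,
    s = g("morphometry", "s", 0.8),
    n_S = g("morphometry", "n_S", 10), n_T = g("morphometry", "n_T", 7),
    eps_S = g("morphometry", "eps_S_deg", 63.9),
    eps_T = g("morphometry", "eps_T_deg", 23),
    kappa = g("morphometry", "kappa_deg", 27))
  ctl <- raw$control
  direction <- if (!is.null(ctl$direction)) ctl$direction else 1
  beat <- beat_params(
    f = 20,
    Phi = g("beat", "Phi_deg", 112), Ta = g("beat", "Ta", 0.3),
    Sa = g("beat", "Sa", 0.3), P_L = g("beat", "P_L", 0.132),
    direction = direction)
  fluid <- fluid_properties(rho = g("fluid", "rho", 1025),
                            nu = g("fluid", "nu", 1.05e-6))
  replay_path <- NULL
  if (is.null(ctl) || length(ctl) == 0) {
    message("empty control block: defaulting to mode4 at f = 20 Hz")
    program <- assign_mode("mode4", f_out = 20)
  } else if (!is.null(ctl$replay)) {
    replay_path <- ctl$replay
    program <- NULL
  } else if (!is.null(ctl$freqs)) {
    program <- row_frequency_program(ctl$freqs, direction = direction)
  } else if (!is.null(ctl$rows)) {
    f <- if (!is.null(ctl$f)) ctl$f else 30
    freqs <- rep(0, 8); freqs[unlist(ctl$rows)] <- f
    program <- row_frequency_program(freqs, direction = direction,
                                     mode_label = "subset")
  } else if (!is.null(ctl$mode)) {
    program <- assign_mode(ctl$mode,
                           f_out = if (!is.null(ctl$f_out)) ctl$f_out else 20,
                           f_in = if (!is.null(ctl$f_in)) ctl$f_in else 0,
                           direction = direction)
  } else stop("control block must give 'mode', 'freqs', 'rows' or 'replay'")
  sim <- list(duration = g("simulation", "duration", 1),
              halting = g("simulation", "halting", "none"),
              max_duration = g("simulation", "max_duration", 10),
              stride = g("simulation", "stride", 5))
  out <- list(trajectory = g("output", "trajectory", NULL),
              metrics = g("output", "metrics", NULL),
              stride = g("output", "stride", 1))
  structure(list(morph = morph, beat = beat, fluid = fluid,
                 program = program, replay = replay_path,
                 simulation = sim, output = out, raw = raw,
                 fingerprint = config_fingerprint(raw)),
            class = "cteno_config")
}

#' Write a run configuration
#'
#' Serialize the raw block structure of a configuration back to YAML; a
#' written-then-read configuration reproduces an identical fingerprint.
#'
#' @param config a `cteno_config` (or a raw nested list of blocks).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "cteno_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Read a landmark track
#'
#' Read a comma-separated table of per-frame 3D coordinates of the three
#' tracked landmarks (apical organ and the two tentacular bulbs). The file
#' must have a header with a time column `t` and coordinate columns
#' `apical_x ... bulb2_z`; coordinates may be in m or mm (`units`).
#'
#' @param path CSV path.
#' @param units `"m"` or `"mm"` for the coordinate columns.
#' @param L body length (m), attached for metric normalization (optional).
#' @return data.frame of class `cteno_landmarks`.
#' @export
read_landmarks <- function(path, units = c("m", "mm"), L = NULL) {
  units <- match.arg(units)
  lm <- utils::read.csv(path)
  need <- c("t", as.vector(outer(c("apical", "bulb1", "bulb2"),
                                 c("x", "y", "z"), paste, sep = "_")))
  miss <- setdiff(need, names(lm))
  if (length(miss))
    stop("landmark table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(lm$t, strictly = TRUE))
    stop("landmark frames must be in strictly increasing time order")
  coord_cols <- setdiff(need, "t")
  if (units == "mm") lm[coord_cols] <- lm[coord_cols] * 1e-3
  # non-degenerate landmark triangle per frame
  ao <- as.matrix(lm[, c("apical_x", "apical_y", "apical_z")])
  b1 <- as.matrix(lm[, c("bulb1_x", "bulb1_y", "bulb1_z")])
  b2 <- as.matrix(lm[, c("bulb2_x", "bulb2_y", "bulb2_z")])
  v1 <- b1 - ao; v2 <- b2 - ao
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  degen <- sqrt(rowSums(cr^2)) < 1e-18
  if (any(degen))
    warning(sprintf("%d frame(s) have a (near-)degenerate landmark triangle",
                    sum(degen)))
  fr <- if (nrow(lm) > 1) (nrow(lm) - 1) / (lm$t[nrow(lm)] - lm$t[1]) else NA
  structure(lm[need], class = c("cteno_landmarks", "data.frame"),
            L = L, frame_rate = fr, degenerate = which(degen))
}

#' Write a landmark track
#'
#' @param lm a `cteno_landmarks` table (SI units).
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(as.data.frame(lm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory with sidecar metadata
#'
#' Write the trajectory table as CSV (9 significant digits, SI units) and a
#' YAML sidecar (`<path>.meta.yaml`) recording the configuration fingerprint,
#' integrator step, body length and control program.
#'
#' @param traj a `cteno_trajectory`.
#' @param path CSV output path.
#' @param fingerprint configuration fingerprint string (optional).
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path, fingerprint = NULL) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(col) signif(col, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(fingerprint = fingerprint,
               dt = attr(traj, "dt"), dt_step = attr(traj, "dt_step"),
               L = attr(traj, "L"), f_max = attr(traj, "f_max"),
               mode_label = attr(traj, "mode_label"),
               direction = attr(traj, "direction"),
               halted = attr(traj, "halted"),
               coefficient_strategies = c(
                 plate = "flat-plate C_inf + alpha/sqrt(Re)",
                 body = "Oberbeck-Stokes x Schiller-Naumann",
                 added_mass = "Lamb potential flow",
                 torque = "creeping-flow spheroid x sqrt(Re) correction"))
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return a `cteno_trajectory` (attributes restored from the sidecar when
#'   present).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  traj <- structure(df, class = c("cteno_trajectory", "data.frame"))
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    for (k in c("dt", "dt_step", "L", "f_max", "mode_label", "direction",
                "halted"))
      if (!is.null(meta[[k]])) attr(traj, k) <- meta[[k]]
  } else {
    attr(traj, "dt") <- stats::median(diff(df$t))
  }
  traj
}

#' Write a motor-volume grid
#'
#' Plain-text output: a YAML metadata header (voxel size, origin, dimensions,
#' count, volume) followed by one occupied voxel index triple per line.
#'
#' @param mv a [motor_volume()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_motor_volume <- function(mv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# motor volume occupancy grid",
               yaml::as.yaml(list(voxel = mv$voxel,
                                  origin = as.numeric(mv$origin),
                                  dims = as.integer(mv$dims),
                                  count = mv$count, volume = mv$volume)),
               "# occupied voxel indices (i j k):"), con)
  if (mv$count > 0)
    utils::write.table(mv$occupied, con, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}
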