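# Canonical pose: every trajectory is translated and rotated so that at its
# first sample the body centroid (or tentacular-bulb midpoint) is at the
# origin, the aboral-oral axis lies along +x (oral end facing +x, so +x is
# forward swimming), and the tentacular plane coincides with the x-y plane.

rigid_transform_traj <- function(traj, Q, origin) {
  P <- as.matrix(traj[, c("x", "y", "z")])
  Pn <- sweep(P, 2, origin) %*% t(Q)
  traj$x <- Pn[, 1]; traj$y <- Pn[, 2]; traj$z <- Pn[, 3]
  if (all(c("vx", "vy", "vz") %in% names(traj))) {
    Vn <- as.matrix(traj[, c("vx", "vy", "vz")]) %*% t(Q)
    traj$vx <- Vn[, 1]; traj$vy <- Vn[, 2]; traj$vz <- Vn[, 3]
  }
  traj
}

#' Canonicalize a trajectory or landmark track
#'
#' Apply the rigid transform that moves the initial pose to the canonical
#' start: origin at the starting point, body axis along +x, tentacular plane
#' in the x-y plane. For a simulated trajectory the initial pose comes from
#' the Euler angles of the first sample; for a landmark track
#' (see [read_landmarks()]) the pose is derived from the three landmarks:
#' the body axis points from the apical organ to the tentacular-bulb
#' midpoint (oral positive), the tentacular plane contains the two bulbs,
#' and the trajectory is the bulb-midpoint path.
#'
#' The operation is idempotent: canonicalizing a canonical trajectory leaves
#' it unchanged.
#'
#' @param x a `cteno_trajectory` or a `cteno_landmarks` object.
#' @return a `cteno_trajectory` in canonical pose (for landmark input, with
#'   columns `t, x, y, z`).
#' @export
canonicalize <- function(x) {
  if (inherits(x, "cteno_landmarks")) {
    ao <- as.matrix(x[, c("apical_x", "apical_y", "apical_z")])
    b1 <- as.matrix(x[, c("bulb1_x", "bulb1_y", "bulb1_z")])
    b2 <- as.matrix(x[, c("bulb2_x", "bulb2_y", "bulb2_z")])
    mid <- (b1 + b2) / 2
    e1 <- mid[1, ] - ao[1, ]                  # aboral -> oral body axis
    n1 <- sqrt(sum(e1^2))
    bb <- b1[1, ] - b2[1, ]                   # in the tentacular plane
    if (n1 < 1e-12 || sqrt(sum(bb^2)) < 1e-12)
      stop("degenerate landmark pose: coincident landmarks in first frame")
    e1 <- e1 / n1
    e2 <- bb - sum(bb * e1) * e1
    n2 <- sqrt(sum(e2^2))
    if (n2 < 1e-12)
      stop("degenerate landmark pose: collinear landmarks in first frame")
    e2 <- e2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    Q <- rbind(e1, e2, e3)                    # global -> body at t0
    traj <- data.frame(t = x$t, x = mid[, 1], y = mid[, 2], z = mid[, 3])
    class(traj) <- c("cteno_trajectory", "data.frame")
    attr(traj, "L") <- attr(x, "L")
    return(rigid_transform_traj(traj, Q, mid[1, ]))
  }
  stopifnot(inherits(x, "cteno_trajectory"))
  Q <- build_rotation_matrix(x$psi[1], x$theta[1], x$phi[1])
  origin <- as.numeric(x[1, c("x", "y", "z")])
  out <- rigid_transform_traj(x, Q, origin)
  # the canonical pose has zero initial Euler angles by construction
  if (all(c("psi", "theta", "phi") %in% names(out))) {
    R0 <- Q
    ang <- t(vapply(seq_len(nrow(out)), function(i) {
      Rn <- build_rotation_matrix(out$psi[i], out$theta[i], out$phi[i]) %*%
        t(R0)
      c(atan2(Rn[1, 2], Rn[1, 1]), asin(-max(-1, min(1, Rn[1, 3]))),
        atan2(Rn[2, 3], Rn[3, 3]))
    }, numeric(3)))
    out$psi <- ang[, 1]; out$theta <- ang[, 2]; out$phi <- ang[, 3]
  }
  out
}
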