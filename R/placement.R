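# Ctene placement on the spheroid surface.
#
# Body frame convention: e1' points aboral -> oral (oral positive), the
# tentacular plane is the e1'-e2' plane and the sagittal plane the e1'-e3'
# plane. A meridian at azimuth eps (measured from the tentacular plane) is
# parametrized by u in [0, pi]:
#   x' = -b cos(u),  y' = a sin(u) cos(eps),  z' = a sin(u) sin(eps)
# with u = 0 at the aboral pole and u = pi at the oral pole.

# arc length along a meridian from the aboral pole to parameter u
meridian_arc_length <- function(morph, u) {
  a <- morph$d_B / 2; b <- morph$L_B / 2
  vapply(u, function(uu) {
    stats::integrate(function(t) sqrt(b^2 * sin(t)^2 + a^2 * cos(t)^2),
                     0, uu, rel.tol = 1e-10)$value
  }, numeric(1))
}

# convert the centroid polar angle kappa (deg, from the aboral pole) into the
# meridian parameter u: the surface point along the ray at angle kappa from
# the -x' axis satisfies tan(kappa) = a sin(u) / (b cos(u))
kappa_to_meridian_angle <- function(morph) {
  a <- morph$d_B / 2; b <- morph$L_B / 2
  atan2(b * tan(morph$kappa * pi / 180), a)
}

# invert the meridian arc length on a dense grid (vectorized over arc)
meridian_angle_at_arc <- function(morph, arc) {
  grid <- seq(0, pi, length.out = 4001)
  s_grid <- c(0, cumsum(arc_segment_lengths(morph, grid)))
  stats::approx(s_grid, grid, xout = arc, rule = 2)$y
}

arc_segment_lengths <- function(morph, grid) {
  a <- morph$d_B / 2; b <- morph$L_B / 2
  f <- function(t) sqrt(b^2 * sin(t)^2 + a^2 * cos(t)^2)
  # Simpson's rule on each grid cell
  h <- diff(grid)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  h / 6 * (f(grid[-length(grid)]) + 4 * f(mid) + f(grid[-1]))
}

#' Row layout of the eight ctene rows
#'
#' Row azimuths (degrees from the tentacular plane) and row types for the
#' eight rows, ordered by body quadrant. Each quadrant formed by the sagittal
#' and tentacular planes holds one sagittal-row/tentacular-row pair; the
#' quadrants are numbered 1 (+y,+z), 2 (-y,+z), 3 (-y,-z), 4 (+y,-z).
#'
#' @param morph a [morphometry()] object.
#' @return data.frame with `row_id` (1-8), `quadrant`, `type`
#'   ("sagittal"/"tentacular"), `eps_deg` and `n` (ctenes in the row).
#' @export
row_layout <- function(morph) {
  stopifnot(inherits(morph, "cteno_morphometry"))
  eS <- morph$eps_S; eT <- morph$eps_T
  data.frame(
    row_id   = 1:8,
    quadrant = rep(1:4, each = 2),
    type     = rep(c("sagittal", "tentacular"), 4),
    eps_deg  = c(eS, eT, 180 - eS, 180 - eT, 180 + eS, 180 + eT, -eS, -eT),
    n        = rep(c(morph$n_S, morph$n_T), 4)
  )
}

#' Place all ctenes on the spheroid surface
#'
#' Positions every ctene of the eight rows on the body surface. Within a row,
#' ctene 1 (the most aboral) sits at polar angle kappa from the aboral pole
#' and successive ctenes advance toward the oral end with meridian arc
#' spacing `delta = s * l`. Each placement carries the local meridian tangent
#' angle `lambda` (the plate oscillation direction makes angle lambda with
#' the body symmetry axis) and the signed row azimuth `eps`.
#'
#' @param morph a [morphometry()] object.
#' @return data.frame of class `cteno_placement` with one row per ctene:
#'   `row_id`, `quadrant`, `type`, `k` (1 = most aboral), body-frame position
#'   `x`, `y`, `z` (m), tangent angle `lambda` (rad) and azimuth `eps` (rad).
#' @export
#' @examples
#' pl <- place_ctenes(morphometry())
#' nrow(pl)            # 4 * n_S + 4 * n_T ctenes
#' mean(pl$x) < 0      # aboral placement bias
place_ctenes <- function(morph) {
  stopifnot(inherits(morph, "cteno_morphometry"))
  a <- morph$d_B / 2; b <- morph$L_B / 2
  rows <- row_layout(morph)
  half <- meridian_arc_length(morph, pi)
  s0 <- meridian_arc_length(morph, kappa_to_meridian_angle(morph))

  out <- lapply(seq_len(nrow(rows)), function(i) {
    n <- rows$n[i]
    arcs <- s0 + (seq_len(n) - 1) * morph$delta
    if (max(arcs) > half)
      stop("ctene row overruns the oral pole")
    u <- meridian_angle_at_arc(morph, arcs)
    eps <- rows$eps_deg[i] * pi / 180
    # meridian tangent toward the oral end: d/du (-b cos u, a sin u * e_r)
    lambda <- atan2(a * cos(u), b * sin(u))
    data.frame(row_id = rows$row_id[i], quadrant = rows$quadrant[i],
               type = rows$type[i], k = seq_len(n),
               x = -b * cos(u), y = a * sin(u) * cos(eps),
               z = a * sin(u) * sin(eps),
               lambda = lambda, eps = eps)
  })
  res <- do.call(rbind, out)
  class(res) <- c("cteno_placement", "data.frame")
  res
}
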