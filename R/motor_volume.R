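#' Voxelized motor volume
#'
#' Estimate the reachable space (motor volume) of a set of canonicalized
#' trajectories as the union of the volumes swept by the body: an oriented
#' prolate spheroid (semi-axes `b` along the body axis, `a` transverse) is
#' placed at every trajectory sample and rasterized onto a common voxel
#' grid; the motor volume is the number of occupied voxels times the voxel
#' volume.
#'
#' @param trajs a `cteno_trajectory` or list of them, in canonical pose. If a
#'   trajectory carries Euler-angle columns the spheroid is oriented
#'   accordingly; otherwise the body axis is taken along the local direction
#'   of motion.
#' @param morphs a [morphometry()] object or list of them (one per
#'   trajectory) giving each body's `L_B` and `d_B`.
#' @param voxel voxel edge length (m). A warning is issued when coarser than
#'   half the semi-minor axis.
#' @param sample_stride use every `sample_stride`-th trajectory sample.
#' @return object of class `cteno_motor_volume`: list with `voxel`, `origin`,
#'   `dims`, `count` (occupied voxels), `volume` (m^3) and `occupied`
#'   (integer matrix of occupied voxel indices).
#' @export
#' @examples
#' tr <- make_fixture("line", list(speed = 0, L = 7.8e-3), n = 3)
#' mv <- motor_volume(tr, morphometry(), voxel = 3e-4)
#' mv$volume   # ~ spheroid volume
motor_volume <- function(trajs, morphs, voxel, sample_stride = 1L) {
  stopifnot(voxel > 0)
  if (inherits(trajs, "cteno_trajectory")) trajs <- list(trajs)
  if (inherits(morphs, "cteno_morphometry"))
    morphs <- rep(list(morphs), length(trajs))
  stopifnot(length(trajs) == length(morphs))
  a_max <- max(vapply(morphs, function(m) m$d_B / 2, numeric(1)))
  b_max <- max(vapply(morphs, function(m) m$L_B / 2, numeric(1)))
  if (voxel > a_max / 2)
    warning("voxel is coarser than half the semi-minor axis; volume will be crude")

  # common grid covering all poses
  allP <- do.call(rbind, lapply(trajs, function(tr)
    as.matrix(tr[, c("x", "y", "z")])))
  lo <- apply(allP, 2, min) - b_max - voxel
  hi <- apply(allP, 2, max) + b_max + voxel
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  occ <- new.env(hash = TRUE, size = 1e5)

  mark <- function(center, axis, a, b) {
    axis <- axis / sqrt(sum(axis^2))
    ilo <- pmax(1L, as.integer(floor((center - b - lo) / voxel)) + 1L)
    ihi <- pmin(dims, as.integer(ceiling((center + b - lo) / voxel)) + 1L)
    if (any(ilo > ihi)) return(invisible())
    gx <- lo[1] + (seq(ilo[1], ihi[1]) - 0.5) * voxel
    gy <- lo[2] + (seq(ilo[2], ihi[2]) - 0.5) * voxel
    gz <- lo[3] + (seq(ilo[3], ihi[3]) - 0.5) * voxel
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d <- sweep(g, 2, center)
    ax <- d %*% axis
    r2 <- rowSums(d^2) - ax^2
    inside <- (ax / b)^2 + r2 / a^2 <= 1
    if (!any(inside)) return(invisible())
    idx <- as.matrix(expand.grid(i = seq(ilo[1], ihi[1]),
                                 j = seq(ilo[2], ihi[2]),
                                 k = seq(ilo[3], ihi[3])))[inside, ,
                                                           drop = FALSE]
    keys <- sprintf("%d_%d_%d", idx[, 1], idx[, 2], idx[, 3])
    for (ii in seq_along(keys)) assign(keys[ii], idx[ii, ], envir = occ)
    invisible()
  }

  for (j in seq_along(trajs)) {
    tr <- trajs[[j]]
    m <- morphs[[j]]
    a <- m$d_B / 2; b <- m$L_B / 2
    rows <- seq(1, nrow(tr), by = sample_stride)
    has_angles <- all(c("psi", "theta", "phi") %in% names(tr))
    for (i in rows) {
      center <- as.numeric(tr[i, c("x", "y", "z")])
      axis <- if (has_angles) {
        R <- build_rotation_matrix(tr$psi[i], tr$theta[i], tr$phi[i])
        as.numeric(crossprod(R, c(1, 0, 0)))
      } else if (i < nrow(tr)) {
        v <- as.numeric(tr[min(i + 1, nrow(tr)), c("x", "y", "z")]) - center
        if (sum(v^2) < 1e-24) c(1, 0, 0) else v
      } else c(1, 0, 0)
      mark(center, axis, a, b)
    }
  }
  keys <- ls(occ)
  occupied <- if (length(keys))
    do.call(rbind, mget(keys, envir = occ)) else matrix(integer(), 0, 3)
  structure(list(voxel = voxel, origin = lo, dims = dims,
                 count = nrow(occupied),
                 volume = nrow(occupied) * voxel^3,
                 occupied = occupied),
            class = "cteno_motor_volume")
}

#' @export
print.cteno_motor_volume <- function(x, ...) {
  cat(sprintf("Motor volume: %d voxels of %.3g mm -> %.4g mm^3\n",
              x$count, x$voxel * 1e3, x$volume * 1e9))
  invisible(x)
}
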