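test_that("mean speed recovers analytic fixtures", {
  # straight line at 10 mm/s with a 7.8 mm body: 1.282 BL/s
  line <- make_fixture("line", list(speed = 10e-3, L = 7.8e-3), n = 60)
  expect_equal(mean_speed(line), 10 / 7.8, tolerance = 1e-9)
  # static trajectory
  still <- make_fixture("line", list(speed = 0, L = 7.8e-3), n = 10)
  expect_equal(mean_speed(still), 0)
  # circle: rho * Omega / L within chord error
  circ <- make_fixture("circle", list(radius = 5e-3, omega = 2, L = 7.8e-3),
                       n = 101)
  expect_equal(mean_speed(circ), 5e-3 * 2 / 7.8e-3, tolerance = 1e-3)
  expect_error(mean_speed(make_fixture("line", list(L = 1e-2), n = 3)[1, ],
                          L = 1e-2), "2 samples")
})

test_that("path curvature recovers line, circle and helix closed forms", {
  for (n in c(60, 200, 1000)) {
    circ <- make_fixture("circle", list(radius = 5e-3, omega = 2, L = 7.8e-3),
                         n = n)
    expect_equal(curvature_radius(circ)$RL_bar, 5e-3 / 7.8e-3,
                 tolerance = 5e-3)
  }
  line <- make_fixture("line", list(speed = 8e-3, L = 7.8e-3), n = 100)
  cl <- curvature_radius(line)
  expect_equal(cl$RL_bar, 10)
  expect_true(cl$straight_flag)
  r <- 4e-3; p <- 2e-3; L <- 7.8e-3
  helix <- make_fixture("helix",
                        list(radius = r, omega = 3, pitch = p, L = L),
                        n = 800)
  R_true <- r * (1 + (p / (2 * pi * r))^2)
  expect_equal(curvature_radius(helix)$RL_bar, R_true / L, tolerance = 0.01)
})

test_that("state-based turning radius matches rigid-body closed forms", {
  # synthetic state: uniform circular motion, radius v/w
  t <- seq(0, 2, length.out = 300)
  v0 <- 6e-3; w0 <- 1.5; L <- 7.8e-3
  tr <- data.frame(t = t,
                   x = v0 / w0 * sin(w0 * t), y = -v0 / w0 * cos(w0 * t),
                   z = 0,
                   vx = v0 * cos(w0 * t), vy = v0 * sin(w0 * t), vz = 0,
                   psi = w0 * t, theta = 0, phi = 0,
                   wx = 0, wy = 0, wz = w0)
  rl <- turning_radius_state(tr, L = L, startup_cycles = 0)
  expect_equal(rl$RL_bar, v0 / w0 / L, tolerance = 1e-12)
  # zero angular velocity clamps to straight swimming
  tr$wz <- 0
  rl0 <- turning_radius_state(tr, L = L, startup_cycles = 0)
  expect_equal(rl0$RL_bar, 10)
  expect_true(rl0$straight_flag)
})

test_that("maneuver metrics dispatch on the available columns", {
  tr <- short_run("mode1", 30, duration = 0.5)
  mm_state <- maneuver_metrics(tr)
  expect_equal(mm_state$RL_bar, turning_radius_state(tr)$RL_bar)
  mm_path <- maneuver_metrics(tr, method = "path")
  expect_equal(mm_path$RL_bar, curvature_radius(tr)$RL_bar)
  # fixtures have no angular velocity: auto falls back to path geometry
  circ <- make_fixture("circle", list(radius = 5e-3, omega = 2, L = 7.8e-3),
                       n = 200)
  expect_equal(maneuver_metrics(circ)$RL_bar,
               curvature_radius(circ)$RL_bar)
  expect_gt(mm_state$V_bar, 0)
})

test_that("MAP table exposes extreme queries", {
  res <- data.frame(mode = c("a", "b", "c"), f_out = c(10, 20, 30),
                    f_in = 0, direction = 1,
                    V_bar = c(0.5, 1.5, 1.0), RL_bar = c(0.3, 2, 0.9))
  map <- build_map(res)
  expect_equal(attr(map, "best_turn")$mode, "a")
  expect_equal(attr(map, "fastest")$mode, "b")
  one <- build_map(res[1, ])
  expect_equal(attr(one, "best_turn")$mode, attr(one, "fastest")$mode)
})

test_that("canonicalization is rigid, idempotent and inverts a known pose", {
  tr <- short_run("mode1", 30, duration = 0.5)
  can <- canonicalize(tr)
  # starts at the origin with zero attitude
  expect_equal(as.numeric(can[1, c("x", "y", "z")]), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(can[1, c("psi", "theta", "phi")]), c(0, 0, 0),
               tolerance = 1e-9)
  # rigid: pairwise distances preserved
  P0 <- as.matrix(tr[, c("x", "y", "z")])
  P1 <- as.matrix(can[, c("x", "y", "z")])
  i <- seq(1, nrow(P0), length.out = 10)
  expect_equal(as.numeric(dist(P1[i, ])), as.numeric(dist(P0[i, ])),
               tolerance = 1e-12)
  # idempotent
  can2 <- canonicalize(can)
  expect_equal(can2$x, can$x, tolerance = 1e-12)
  expect_equal(can2$psi, can$psi, tolerance = 1e-12)
  # a simulated trajectory already starts canonical
  expect_equal(can$x, tr$x, tolerance = 1e-12)
  expect_equal(can$z, tr$z, tolerance = 1e-12)
})

test_that("canonicalization recovers a known landmark pose", {
  lm <- make_fixture("landmark_pose",
                     list(yaw = 30 * pi / 180, pitch = -0.2, roll = 0.1,
                          speed = 5e-3, L = 7.8e-3,
                          offset = c(2e-3, -1e-3, 3e-3)), n = 40)
  can <- canonicalize(lm)
  expect_equal(as.numeric(can[1, c("x", "y", "z")]), c(0, 0, 0),
               tolerance = 1e-12)
  # the body moves along its own axis, so the canonical path is along +x
  expect_equal(can$y, rep(0, nrow(can)), tolerance = 1e-9)
  expect_equal(can$z, rep(0, nrow(can)), tolerance = 1e-9)
  expect_equal(max(can$x), 5e-3, tolerance = 1e-9)
})

test_that("degenerate landmark poses are rejected", {
  lm <- make_fixture("landmark_pose", list(L = 7.8e-3), n = 5)
  bad <- lm
  bad[1, c("bulb2_x", "bulb2_y", "bulb2_z")] <-
    bad[1, c("bulb1_x", "bulb1_y", "bulb1_z")]
  # coincident bulbs leave the tentacular direction undefined
  expect_error(canonicalize(bad), "degenerate")
})

test_that("motor volume approximates the swept-body volume", {
  m <- morphometry()
  still <- make_fixture("line", list(speed = 0, L = m$L_B), n = 3)
  a <- m$d_B / 2; b <- m$L_B / 2
  mv <- motor_volume(still, m, voxel = a / 10)
  expect_equal(mv$volume / (4 / 3 * pi * a^2 * b), 1, tolerance = 0.03)
  expect_equal(mv$volume, mv$count * mv$voxel^3)
  # union monotonicity: adding a second displaced pose cannot shrink it
  line <- make_fixture("line", list(speed = 5e-3, L = m$L_B), n = 5)
  mv2 <- motor_volume(list(still, line), m, voxel = a / 10)
  expect_gte(mv2$count, mv$count)
  # coarse voxel warns
  expect_warning(motor_volume(still, m, voxel = a), "coarse")
})

test_that("motor-volume occupancy is symmetric for mirrored trajectories", {
  m <- morphometry()
  a <- m$d_B / 2
  arc <- make_fixture("circle", list(radius = 4e-3, omega = 2, L = m$L_B,
                                     turns = 0.25), n = 20)
  arc_m <- arc; arc_m$y <- -arc_m$y
  mv <- motor_volume(list(arc, arc_m), m, voxel = a / 6)
  occ <- mv$occupied
  # reflect indices through the grid plane closest to y = 0
  y0 <- (0 - mv$origin[2]) / mv$voxel + 0.5
  refl <- occ; refl[, 2] <- round(2 * y0 - occ[, 2])
  key <- function(M) paste(M[, 1], M[, 2], M[, 3])
  expect_gt(mean(key(refl) %in% key(occ)), 0.95)
})

test_that("motor-volume estimate converges under voxel refinement", {
  m <- morphometry()
  a <- m$d_B / 2
  still <- make_fixture("line", list(speed = 0, L = m$L_B), n = 3)
  v1 <- motor_volume(still, m, voxel = a / 6)$volume
  v2 <- motor_volume(still, m, voxel = a / 12)$volume
  expect_lt(abs(v2 - v1) / v1, 0.02)
})
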