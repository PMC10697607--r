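test_that("coefficient model obeys its limits and monotonicity", {
  # sphere degeneracy
  sph <- default_coefficients(2e-3, 2e-3)
  expect_equal(sph$Cm_par, 0.5)
  expect_equal(sph$Cm_perp, 0.5)
  expect_equal(sph$K_par, sph$K_perp)
  expect_equal(sph$G_par, sph$G_perp, tolerance = 1e-10)
  # Stokes limit of the sphere drag correlation
  C <- body_drag_coefficients(0.01, sph)
  expect_equal(C$par, 24 / 0.01, tolerance = 0.05 * 24 / 0.01)
  # decreasing in Re
  C10 <- body_drag_coefficients(10, tcoef)
  C100 <- body_drag_coefficients(100, tcoef)
  C1000 <- body_drag_coefficients(1000, tcoef)
  expect_gt(C10$par, C100$par); expect_gt(C100$par, C1000$par)
  expect_gt(C10$perp, C100$perp); expect_gt(C100$perp, C1000$perp)
  # prolate body: axial added mass below lateral (Lamb closed forms)
  expect_lt(tcoef$Cm_par, 0.5)
  expect_gt(tcoef$Cm_perp, 0.5)
  expect_lt(tcoef$Cm_par, tcoef$Cm_perp)
  # all coefficients non-negative across the validity band
  Re <- 10^seq(-2, 4, length.out = 30)
  expect_true(all(plate_drag_coefficient(Re, tcoef) >= 0))
  expect_true(all(unlist(body_drag_coefficients(Re, tcoef)) >= 0))
  expect_true(all(unlist(rotation_torque_coefficients(Re, tcoef)) >= 0))
})

test_that("Oberbeck shape factors reproduce creeping-flow spheroid drag", {
  # drag in the Stokes limit must equal mu * U * D with Oberbeck's D
  U <- 1e-5                       # deep creeping flow
  fl <- tfluid
  FD <- body_drag(c(U, 0, 0), diag(3), tbody, fl, tcoef)
  e <- tcoef$e; b <- tbody$b
  Lg <- log((1 + e) / (1 - e))
  D_par <- 16 * pi * e^3 * b / ((1 + e^2) * Lg - 2 * e)
  mu <- fl$rho * fl$nu
  # divide out the finite-Re correction factor to isolate the Stokes limit
  corr <- 1 + tcoef$c1 * (U * tm$L_B / fl$nu)^tcoef$c2
  expect_equal(-FD[1] / corr / (mu * U * D_par), 1, tolerance = 1e-9)
})

test_that("single-plate force matches the hand-evaluated drag expression", {
  pl1 <- tplac[1, ]
  u_tip <- 0.04
  st <- data.frame(x_A = 0, y_A = tm$l, x_A_dot = u_tip, y_A_dot = 0,
                   w = 0.5 * tm$l)
  F <- ctene_forces(pl1, st, c(0, 0, 0), diag(3), tfluid, tcoef)
  Re_p <- u_tip * tm$l / tfluid$nu
  C_A <- plate_drag_coefficient(Re_p, tcoef)
  expect_equal(sqrt(sum(F^2)),
               tfluid$rho * 0.5 * tm$l / 2 * tm$l * C_A * u_tip^2,
               tolerance = 1e-12)
  # directed opposite the plate velocity
  u <- plate_velocity_global(st, diag(3), pl1)
  expect_lt(sum(F * u), 0)
  expect_equal(abs(sum(F * u)) / sqrt(sum(F^2)) / sqrt(sum(u^2)), 1,
               tolerance = 1e-12)
  # stationary plates contribute nothing
  st0 <- st; st0$x_A_dot <- 0
  expect_equal(as.numeric(ctene_forces(pl1, st0, c(1e-3, 0, 0), diag(3),
                                       tfluid, tcoef)), c(0, 0, 0))
  expect_error(ctene_forces(pl1, transform(st, x_A_dot = NaN), c(0, 0, 0),
                            diag(3), tfluid, tcoef), "non-finite")
})

test_that("cycle-averaged row thrust opposes the power-stroke sweep", {
  # one sagittal row beating on a held body: net force over a cycle points
  # oral-ward (+x) for the forward power stroke, aboral for reversed
  bp <- beat_params(f = 30)
  row1 <- tplac[tplac$row_id == 1, ]
  cyc <- function(direction) {
    b <- beat_params(f = 30, direction = direction)
    ts <- seq(0, 1 / 30, length.out = 241)[-241]
    F <- sapply(ts, function(t) {
      st <- do.call(rbind, lapply(row1$k, function(k)
        tip_state(t, b, tm$l, phase_offset(k, b))))
      # near stroke reversal the plate Reynolds number drops below the
      # validity band and is clamped with a warning; that is expected here
      suppressWarnings(row_force(row1, st, c(0, 0, 0), diag(3), tfluid,
                                 tcoef))
    })
    rowMeans(F)
  }
  Ff <- cyc(1); Fb <- cyc(-1)
  expect_gt(Ff[1], 0)
  expect_lt(Fb[1], 0)
})

test_that("net force equals the brute-force per-ctene accumulation", {
  set.seed(31)
  for (rep in 1:5) {
    ang <- runif(3, -1, 1)
    R <- build_rotation_matrix(ang[1], ang[2], ang[3])
    V <- rnorm(3, sd = 5e-3)
    t <- runif(1, 0, 0.2)
    prog <- row_frequency_program(sample(c(0, 10, 20, 30), 8, replace = TRUE))
    f <- prog$freqs[tplac$row_id]
    st <- do.call(rbind, lapply(seq_len(nrow(tplac)), function(i) {
      bp <- beat_params(f = f[i], Phi = 112, Ta = 0.3, Sa = 0.3, P_L = 0.132)
      tip_state(t, bp, tm$l, phase_offset(tplac$k[i], bp))
    }))
    Fc <- ctene_forces(tplac, st, V, R, tfluid, tcoef)
    # per-row sums, then net, versus the flat per-ctene sum
    rows <- lapply(1:8, function(r)
      row_force(tplac[tplac$row_id == r, ], st[tplac$row_id == r, ],
                V, R, tfluid, tcoef))
    expect_lt(max(abs(net_force(rows) - colSums(Fc))) /
                max(abs(colSums(Fc))), 1e-10)
    # brute-force loop over single ctenes
    brute <- Reduce(`+`, lapply(seq_len(nrow(tplac)), function(i)
      as.numeric(ctene_forces(tplac[i, ], st[i, ], V, R, tfluid, tcoef))))
    expect_lt(max(abs(net_force(rows) - brute)) / max(abs(brute)), 1e-10)
  }
})

test_that("propulsive torque is the body-frame moment of the plate forces", {
  # force parallel to its own position vector gives no torque
  pl1 <- tplac[1, ]
  F_par <- matrix(as.numeric(pl1[c("x", "y", "z")]), 1)
  expect_equal(propulsive_torque(pl1, F_par, diag(3)), c(0, 0, 0))
  # fully symmetric activation cancels the net torque
  bp <- beat_params(f = 20)
  st <- do.call(rbind, lapply(seq_len(nrow(tplac)), function(i)
    tip_state(0.013, bp, tm$l, phase_offset(tplac$k[i], bp))))
  Fc <- ctene_forces(tplac, st, c(0, 0, 0), diag(3), tfluid, tcoef)
  tau <- propulsive_torque(tplac, Fc, diag(3))
  scale <- sum(abs(as.matrix(tplac[, c("x", "y", "z")])) %*% rep(1, 3) *
                 sqrt(rowSums(Fc^2)))
  expect_lt(max(abs(tau)), 1e-12 * scale)
  # two adjacent rows on one side turn the body toward the inactive side:
  # quadrant-1 rows (+y, +z side) active -> torque tips the oral axis away
  act <- tplac$quadrant == 1
  tau1 <- propulsive_torque(tplac[act, ], Fc[act, ], diag(3))
  expect_gt(sqrt(tau1[2]^2 + tau1[3]^2), abs(tau1[1]) * 10)
})

test_that("body drag is dissipative and frame-consistent", {
  expect_equal(body_drag(c(0, 0, 0), diag(3), tbody, tfluid, tcoef),
               c(0, 0, 0))
  # axial motion closed form
  U <- 8e-3
  C <- body_drag_coefficients(U * tm$L_B / tfluid$nu, tcoef)
  FD <- body_drag(c(U, 0, 0), diag(3), tbody, tfluid, tcoef)
  expect_equal(FD, c(-tfluid$rho / 2 * pi * tbody$a^2 * C$par * U^2, 0, 0),
               tolerance = 1e-12)
  angs <- rand_angles(8, seed = 41)
  set.seed(42)
  for (i in 1:8) {
    R <- build_rotation_matrix(angs[i, 1], angs[i, 2], angs[i, 3])
    v <- rnorm(3, sd = 8e-3)
    FD <- body_drag(v, R, tbody, tfluid, tcoef)
    expect_lte(sum(FD * v), 0)                     # drag power <= 0
    # computing in the body frame and rotating out equals rotating first
    vb <- as.numeric(R %*% v)
    FDb <- body_drag(vb, diag(3), tbody, tfluid, tcoef)
    expect_lt(max(abs(as.numeric(R %*% FD) - FDb)) / max(abs(FDb)), 1e-12)
  }
})

test_that("added-mass force follows the potential-flow tensor", {
  expect_equal(added_mass_force(c(0, 0, 0), diag(3), tbody, tfluid, tcoef),
               c(0, 0, 0))
  sphb <- build_body(morphometry(L_B = 6e-3, d_B = 6e-3), tfluid)
  sphc <- default_coefficients(sphb$a, sphb$b)
  acc <- c(1e-3, -2e-3, 5e-4)
  expect_equal(added_mass_force(acc, diag(3), sphb, tfluid, sphc),
               -0.5 * tfluid$rho * sphb$V * acc, tolerance = 1e-12)
  # prolate: axial acceleration meets less added mass than lateral
  Fax <- added_mass_force(c(1e-3, 0, 0), diag(3), tbody, tfluid, tcoef)
  Flat <- added_mass_force(c(0, 1e-3, 0), diag(3), tbody, tfluid, tcoef)
  expect_lt(abs(Fax[1]), abs(Flat[2]))
})

test_that("opposing torque resists every angular-velocity component", {
  expect_equal(opposing_torque(c(0, 0, 0), tbody, tfluid, tcoef), c(0, 0, 0))
  set.seed(51)
  for (i in 1:10) {
    w <- rnorm(3, sd = 3)
    Tq <- opposing_torque(w, tbody, tfluid, tcoef)
    expect_true(all(sign(Tq[w != 0]) == -sign(w[w != 0])))
    expect_lte(sum(Tq * w), 0)
  }
  # quadratic scaling at fixed coefficients: compare against the closed form
  w <- c(0, 2, 0)
  r_e <- tbody$d_e / 2
  C <- rotation_torque_coefficients(2 * r_e^2 / tfluid$nu, tcoef)
  expect_equal(opposing_torque(w, tbody, tfluid, tcoef)[2],
               -tfluid$rho / 2 * r_e^5 * C$perp * 4, tolerance = 1e-12)
})

test_that("mirror reflection of the configuration reflects the forces", {
  # reflect through the sagittal plane (y -> -y): placements map onto each
  # other, so reflecting the body velocity reflects the force field
  bp <- beat_params(f = 25)
  st <- do.call(rbind, lapply(seq_len(nrow(tplac)), function(i)
    tip_state(0.017, bp, tm$l, phase_offset(tplac$k[i], bp))))
  V <- c(2e-3, 1e-3, -3e-3)
  Fc <- ctene_forces(tplac, st, V, diag(3), tfluid, tcoef)
  net <- colSums(Fc)
  # mirrored configuration: same layout (by symmetry), mirrored velocity
  Vm <- c(V[1], -V[2], V[3])
  Fm <- ctene_forces(tplac, st, Vm, diag(3), tfluid, tcoef)
  netm <- colSums(Fm)
  expect_lt(max(abs(netm - c(net[1], -net[2], net[3]))) / max(abs(net)),
            1e-10)
})

test_that("Reynolds numbers follow the printed definitions", {
  r <- reynolds(U = 2.7 * 7.8e-3, L = 7.8e-3, f = 34, l = 0.5e-3,
                nu = 1.05e-6)
  expect_equal(unname(r["Re_b"]), 156.5, tolerance = 1e-3)
  expect_equal(unname(r["Re_omega"]), 2 * pi * 34 * (0.5e-3)^2 / 1.05e-6)
  expect_equal(unname(reynolds(0, 1e-2, 10, 1e-3, 1e-6)["Re_b"]), 0)
  # quadratic in the appendage length
  r2 <- reynolds(1e-2, 1e-2, 10, sqrt(2) * 1e-3, 1e-6)
  r1 <- reynolds(1e-2, 1e-2, 10, 1e-3, 1e-6)
  expect_equal(unname(r2["Re_omega"] / r1["Re_omega"]), 2)
})
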